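# Independent oracles: brute-force or closed-form reference
# implementations used to verify package results. They deliberately
# avoid the code paths (and, where possible, the base functions) used
# by the implementation.

# two-sided Fisher exact p by explicit enumeration with lchoose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  if (m == 0 || n_ == 0 || k == 0 || (c + d) == 0) return(1)
  lo <- max(0, k - n_); hi <- min(k, m)
  ks <- lo:hi
  logp <- lchoose(m, ks) + lchoose(n_, k - ks) - lchoose(m + n_, k)
  p <- exp(logp)
  obs <- p[ks == a]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# mid-ranks computed by hand
oracle_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

# Spearman rho as Pearson correlation of mid-ranks, via explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_midrank(x); ry <- oracle_midrank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# Benjamini-Hochberg adjusted values straight from the step-up
# definition: adj_(i) = min_{j >= i} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# strand-aware donor/acceptor of one junction row
oracle_sites <- function(j) {
  if (j$strand == "+") c(donor = j$intron_start, acceptor = j$intron_end)
  else c(donor = j$intron_end, acceptor = j$intron_start)
}

# exhaustive pair scan for alternative splice-site events
brute_alt_ss_keys <- function(junctions) {
  junctions <- junctions[!duplicated(paste(junctions$chrom,
                                           junctions$strand,
                                           junctions$intron_start,
                                           junctions$intron_end)), ]
  junctions <- junctions[junctions$strand %in% c("+", "-"), ]
  keys <- character(0)
  n <- nrow(junctions)
  if (n < 2) return(keys)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      ji <- junctions[i, ]; jk <- junctions[k, ]
      if (ji$chrom != jk$chrom || ji$strand != jk$strand) next
      si <- oracle_sites(ji); sk <- oracle_sites(jk)
      if (si["donor"] == sk["donor"] && si["acceptor"] != sk["acceptor"]) {
        acc <- sort(c(si["acceptor"], sk["acceptor"]))
        keys <- c(keys, sprintf("A3SS|%s|%s|%d|%d/%d", ji$chrom,
                                ji$strand, si["donor"], acc[1], acc[2]))
      }
      if (si["acceptor"] == sk["acceptor"] && si["donor"] != sk["donor"]) {
        don <- sort(c(si["donor"], sk["donor"]))
        keys <- c(keys, sprintf("A5SS|%s|%s|%d/%d|%d", ji$chrom,
                                ji$strand, don[1], don[2], si["acceptor"]))
      }
    }
  }
  sort(unique(keys))
}

# exhaustive scan over (junction, internal exon, junction, junction)
brute_es_keys <- function(junctions, annotation) {
  ex <- annotation$exons[annotation$exons$internal, ]
  jk <- paste(junctions$chrom, junctions$strand, junctions$intron_start,
              junctions$intron_end, sep = "|")
  keys <- character(0)
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    for (e in seq_len(nrow(ex))) {
      x <- ex[e, ]
      if (x$chrom != j$chrom || x$strand != j$strand) next
      if (!(x$start > j$intron_start && x$end < j$intron_end)) next
      up <- paste(j$chrom, j$strand, j$intron_start, x$start, sep = "|")
      dn <- paste(j$chrom, j$strand, x$end, j$intron_end, sep = "|")
      if (up %in% jk && dn %in% jk) {
        keys <- c(keys, sprintf("ES|%s|%s|%d-%d|%d-%d", j$chrom,
                                j$strand, x$start, x$end,
                                j$intron_start, j$intron_end))
      }
    }
  }
  sort(unique(keys))
}

# per-base coverage check for intron retention
brute_ir_keys <- function(junctions, coverage) {
  keys <- character(0)
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, ]
    bases <- j$intron_start:(j$intron_end - 1L)
    depth <- vapply(bases, function(b) {
      sum(coverage$depth[coverage$chrom == j$chrom &
                           coverage$start <= b & coverage$end > b])
    }, numeric(1))
    if (all(depth >= 1)) {
      keys <- c(keys, sprintf("IR|%s|%s|%d-%d", j$chrom, j$strand,
                              j$intron_start, j$intron_end))
    }
  }
  sort(unique(keys))
}

# random stranded junction set on a small coordinate lattice; designed
# to produce shared donors/acceptors frequently
random_junctions <- function(n, seed) {
  set.seed(seed)
  sites <- sort(sample(seq(100, 2000, by = 50), 12))
  rows <- list()
  for (i in seq_len(n)) {
    ab <- sort(sample(sites, 2))
    rows[[i]] <- jrow("chr1", ab[1], ab[2],
                      sample(c("+", "-"), 1), count = 10L)
  }
  j <- do.call(rbind, rows)
  j[!duplicated(paste(j$chrom, j$strand, j$intron_start, j$intron_end)), ]
}
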