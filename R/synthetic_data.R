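# Seeded synthetic-data generator. Emits exactly the formats the
# pipeline consumes (GFF3 annotation, junction TSV, bedGraph coverage,
# fragment-count TSV) for N individuals, together with ground truth, so
# every stage is testable without external data.
#
# Sampling model: each event has a true long-isoform frequency p (Beta
# distributed); in each individual the informative junction depth n is
# Poisson and the inclusion count is Binomial(n, p_individual). Binomial
# sampling (no overdispersion) matches the sampling assumption of the
# Fisher exact test, so null simulations are calibrated. A configurable
# fraction of events carries a group-level shift in p, and another
# fraction is emitted with sub-threshold support (read count 1) to
# exercise the junction filter.

#' Simulation settings
#'
#' Defaults emulate the statistical structure of a 20-individual xylem
#' RNA-seq study: 12 southern and 8 northern individuals, an AS-type
#' mixture of 40% IR / 32% A3SS / 20% A5SS / 8% ES, mean informative
#' junction depth of 42 reads, and Beta(2,2)-distributed base
#' long-isoform frequencies.
#'
#' @param seed Integer seed; fully determines all outputs.
#' @param n_genes Number of genes to simulate.
#' @param individuals Individual IDs. Default: PT02..PT21.
#' @param groups Named group label per individual. Default: PT02-PT13
#'   southern, PT14-PT21 northern (when using the default individuals),
#'   otherwise a single group.
#' @param exon_range Min/max exons per gene.
#' @param exon_len,intron_len Min/max exon and intron lengths (bp).
#' @param as_mixture Named target proportions over IR/A3SS/A5SS/ES;
#'   must sum to 1.
#' @param event_prob Probability that a gene hosts one AS event.
#' @param beta_shape Two shape parameters of the base-frequency Beta.
#' @param shift_fraction Fraction of events with a true frequency shift
#'   between individuals.
#' @param shift_size Size of the shift in p.
#' @param shift_scope `"individual"`: one randomly chosen individual per
#'   shifted event deviates (individual-specific splicing);
#'   `"group"`: every individual of `shift_group` deviates.
#' @param shift_group Group receiving the shift when
#'   `shift_scope = "group"`.
#' @param depth_mean Mean of the Poisson informative-depth per event and
#'   of constitutive junction read counts.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal parameters of true gene
#'   expression before library normalization.
#' @param low_expr_fraction Fraction of genes forced to near-zero
#'   expression (to exercise the FPKM filter).
#' @param below_support_fraction Fraction of events emitted with read
#'   count 1 so they fail the junction support filter.
#' @param gap_intron_fraction Fraction of non-event introns given
#'   coverage with a 1-base internal gap (intron-retention decoys).
#' @return A list of class `spl_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 100L,
                              individuals = sprintf("PT%02d", 2:21),
                              groups = NULL,
                              exon_range = c(4L, 8L),
                              exon_len = c(80L, 300L),
                              intron_len = c(80L, 250L),
                              as_mixture = c(IR = 0.40, A3SS = 0.32,
                                             A5SS = 0.20, ES = 0.08),
                              event_prob = 0.6,
                              beta_shape = c(2, 2),
                              shift_fraction = 0.15,
                              shift_size = 0.3,
                              shift_scope = c("individual", "group"),
                              shift_group = "northern",
                              depth_mean = 42,
                              fpkm_meanlog = log(20),
                              fpkm_sdlog = 1,
                              low_expr_fraction = 0.05,
                              below_support_fraction = 0.05,
                              gap_intron_fraction = 0.1) {
  if (is.null(groups)) {
    if (identical(individuals, sprintf("PT%02d", 2:21))) {
      groups <- stats::setNames(
        c(rep("southern", 12L), rep("northern", 8L)), individuals)
    } else {
      groups <- stats::setNames(rep("all", length(individuals)),
                                individuals)
    }
  }
  if (abs(sum(as_mixture) - 1) > 1e-8) stop("as_mixture must sum to 1")
  if (!all(c("IR", "A3SS", "A5SS", "ES") %in% names(as_mixture))) {
    stop("as_mixture needs names IR, A3SS, A5SS, ES")
  }
  if (as_mixture[["ES"]] > 0 && exon_range[2L] < 3L) {
    stop("exon skipping requires genes with at least 3 exons")
  }
  if (shift_size < 0 || shift_size >= 1) stop("shift_size must be in [0,1)")
  shift_scope <- match.arg(shift_scope)
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 individuals = individuals, groups = groups[individuals],
                 exon_range = exon_range, exon_len = exon_len,
                 intron_len = intron_len, as_mixture = as_mixture,
                 event_prob = event_prob, beta_shape = beta_shape,
                 shift_fraction = shift_fraction, shift_size = shift_size,
                 shift_scope = shift_scope, shift_group = shift_group,
                 depth_mean = depth_mean,
                 fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
                 low_expr_fraction = low_expr_fraction,
                 below_support_fraction = below_support_fraction,
                 gap_intron_fraction = gap_intron_fraction),
            class = "spl_sim_config")
}

#' Generate a synthetic genome annotation with ground truth
#'
#' Lays out `n_genes` multi-exon genes (10 per chromosome, random
#' strand) and plants at most one AS event per hosting gene, with type
#' drawn from the configured mixture. Event anchors follow the same
#' conventions as the detectors, so truth keys match catalog keys.
#' Writing the GFF3 is byte-deterministic under the seed.
#'
#' @param cfg A [simulation_config()].
#' @param gff3_path Where to write the annotation GFF3.
#' @return The ground truth: a list of class `spl_truth` with `version`,
#'   `individuals`, `groups`, `genes` (incl. true FPKM per gene),
#'   `events` (type, anchors, key, gene, base frequency, shift and
#'   support-failure flags) and `gap_introns` (decoy intervals).
#' @export
generate_genome <- function(cfg, gff3_path) {
  stopifnot(inherits(cfg, "spl_sim_config"))
  set.seed(cfg$seed)
  if (cfg$as_mixture[["ES"]] > 0 && cfg$exon_range[1L] < 3L) {
    # ES host genes must have an internal exon; with a low minimum the
    # host is re-drawn, so require a feasible floor instead
    stop("exon_range minimum must be >= 3 when ES events are requested")
  }

  genes <- vector("list", cfg$n_genes)
  exon_rows <- vector("list", cfg$n_genes)
  cursor <- 0L
  for (g in seq_len(cfg$n_genes)) {
    chrom <- paste0("chr", (g - 1L) %/% 10L + 1L)
    if (g %% 10L == 1L) cursor <- 0L
    n_ex <- sample(cfg$exon_range[1L]:cfg$exon_range[2L], 1L)
    elen <- sample(cfg$exon_len[1L]:cfg$exon_len[2L], n_ex, replace = TRUE)
    ilen <- sample(cfg$intron_len[1L]:cfg$intron_len[2L],
                   max(n_ex - 1L, 0L), replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    start <- cursor + 5000L
    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- start
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + elen[e]
      pos <- ends[e] + if (e < n_ex) ilen[e] else 0L
    }
    cursor <- pos
    gene_id <- sprintf("GENE%04d", g)
    genes[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                             strand = strand, n_exons = n_ex,
                             stringsAsFactors = FALSE)
    exon_rows[[g]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 strand = strand, exon = seq_len(n_ex),
                                 start = starts, end = ends,
                                 stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exon_rows)

  # true expression: log-normal, a slice forced near zero, then scaled
  # so that sum(fpkm * kb) = 1e6 and Poisson fragment counts at these
  # rates recompute to approximately the true FPKM
  fpkm <- stats::rlnorm(cfg$n_genes, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
  low <- stats::runif(cfg$n_genes) < cfg$low_expr_fraction
  fpkm[low] <- fpkm[low] * 1e-4
  kb <- tapply(exons$end - exons$start, exons$gene_id, sum)[genes$gene_id] / 1000
  fpkm <- fpkm * 1e6 / sum(fpkm * kb)
  genes$true_fpkm <- fpkm
  genes$exonic_length <- as.integer(kb * 1000)

  # event placement
  ev <- list()
  types <- names(cfg$as_mixture)
  for (g in seq_len(nrow(genes))) {
    if (stats::runif(1) >= cfg$event_prob) next
    type <- sample(types, 1L, prob = as.numeric(cfg$as_mixture))
    ex <- exon_rows[[g]]
    n_ex <- nrow(ex)
    if (type == "ES" && n_ex < 3L) next
    strand <- ex$strand[1L]
    chrom <- ex$chrom[1L]
    shifted <- stats::runif(1) < cfg$shift_fraction
    repeat {
      p <- stats::rbeta(1, cfg$beta_shape[1L], cfg$beta_shape[2L])
      hi <- if (shifted) 0.95 - cfg$shift_size else 0.95
      if (p >= 0.05 && p <= hi) break
    }
    fail <- stats::runif(1) < cfg$below_support_fraction
    intr_start <- ex$end[-n_ex]
    intr_end <- ex$start[-1L]
    if (type == "IR") {
      i <- sample(n_ex - 1L, 1L)
      a <- c(intr_start[i], intr_end[i], NA_integer_, NA_integer_)
    } else if (type == "ES") {
      j <- sample(2:(n_ex - 1L), 1L)
      a <- c(ex$start[j], ex$end[j], ex$end[j - 1L], ex$start[j + 1L])
    } else {
      i <- sample(n_ex - 1L, 1L)
      s <- intr_start[i]; e <- intr_end[i]
      shift <- sample(20:min(60L, e - s - 20L), 1L)
      if (type == "A3SS") {
        # shared donor, alternative acceptors
        if (strand == "+") a <- c(s, sort(c(e, e - shift)), NA_integer_)
        else a <- c(e, sort(c(s, s + shift)), NA_integer_)
      } else {
        # shared acceptor, alternative donors
        if (strand == "+") a <- c(e, sort(c(s, s + shift)), NA_integer_)
        else a <- c(s, sort(c(e, e - shift)), NA_integer_)
      }
    }
    shift_ind <- if (shifted && cfg$shift_scope == "individual") {
      sample(cfg$individuals, 1L)
    } else NA_character_
    ev[[length(ev) + 1L]] <- data.frame(
      event_type = type, chrom = chrom, strand = strand,
      a1 = a[1L], a2 = a[2L], a3 = a[3L], a4 = a[4L],
      gene_id = genes$gene_id[g], p_base = p, shifted = shifted,
      shift_individual = shift_ind,
      fail_support = fail, stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(event_type = character(), chrom = character(),
               strand = character(), a1 = integer(), a2 = integer(),
               a3 = integer(), a4 = integer(), gene_id = character(),
               p_base = numeric(), shifted = logical(),
               shift_individual = character(),
               fail_support = logical(), stringsAsFactors = FALSE)
  if (nrow(events)) {
    events$key <- make_event_key(events$event_type, events$chrom,
                                 events$strand, events$a1, events$a2,
                                 events$a3, events$a4)
  } else {
    events$key <- character(0)
  }

  # decoy introns: covered except one internal base; never IR
  used <- events$gene_id
  gap <- list()
  for (g in seq_len(nrow(genes))) {
    if (genes$gene_id[g] %in% used) next
    if (stats::runif(1) >= cfg$gap_intron_fraction) next
    ex <- exon_rows[[g]]
    if (nrow(ex) < 2L) next
    i <- sample(nrow(ex) - 1L, 1L)
    gap[[length(gap) + 1L]] <- data.frame(
      chrom = ex$chrom[1L], strand = ex$strand[1L],
      start = ex$end[i], end = ex$start[i + 1L],
      gene_id = ex$gene_id[1L], stringsAsFactors = FALSE)
  }
  gap <- if (length(gap)) do.call(rbind, gap) else
    data.frame(chrom = character(), strand = character(),
               start = integer(), end = integer(),
               gene_id = character(), stringsAsFactors = FALSE)

  write_sim_gff3(genes, exons, gff3_path)

  structure(list(version = 1L, individuals = cfg$individuals,
                 groups = cfg$groups, genes = genes, exons = exons,
                 events = events, gap_introns = gap),
            class = "spl_truth")
}

write_sim_gff3 <- function(genes, exons, path) {
  lines <- character(0)
  for (g in seq_len(nrow(genes))) {
    ex <- exons[exons$gene_id == genes$gene_id[g], , drop = FALSE]
    gid <- genes$gene_id[g]
    tid <- paste0(gid, ".1")
    lines <- c(lines,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom[g], min(ex$start) + 1L, max(ex$end),
                       genes$strand[g], gid),
               sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       genes$chrom[g], min(ex$start) + 1L, max(ex$end),
                       genes$strand[g], tid, gid),
               sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       ex$chrom, ex$start + 1L, ex$end, ex$strand, tid))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# per-individual p for every truth event
truth_frequencies <- function(truth, cfg, individual_id) {
  p <- truth$events$p_base
  if (!nrow(truth$events)) return(p)
  hit <- if (cfg$shift_scope == "individual") {
    truth$events$shifted &
      !is.na(truth$events$shift_individual) &
      truth$events$shift_individual == individual_id
  } else {
    truth$events$shifted &
      truth$groups[[individual_id]] == cfg$shift_group
  }
  ifelse(hit, pmin(p + cfg$shift_size, 0.99), p)
}

#' Simulate the evidence files of one individual
#'
#' Draws, for every truth event, an informative depth n ~ Poisson and an
#' inclusion count ~ Binomial(n, p) at that individual's true frequency,
#' distributes the reads over the event's member junctions (retained
#' introns additionally receive full-length coverage at the inclusion
#' depth), emits Poisson read counts for constitutive junctions, decoy
#' coverage with a one-base gap for gap introns, and Poisson fragment
#' counts at the gene's true expression rate. Events marked as failing
#' support are written with read count 1 at a repetitive position and a
#' 3-bp overhang, which fails every filter criterion.
#'
#' @param truth An `spl_truth` from [generate_genome()].
#' @param cfg The same [simulation_config()].
#' @param individual_id One of `cfg$individuals`.
#' @param dir Output directory; files `<id>.junctions.tsv`,
#'   `<id>.coverage.bedgraph`, `<id>.counts.tsv` are written there.
#' @return Invisibly, a list with the three file paths and the realized
#'   per-event `(n, inclusion)` draws.
#' @export
simulate_individual <- function(truth, cfg, individual_id, dir = ".") {
  stopifnot(inherits(truth, "spl_truth"), inherits(cfg, "spl_sim_config"))
  idx <- match(individual_id, truth$individuals)
  if (is.na(idx)) stop("unknown individual: ", individual_id)
  set.seed((cfg$seed + 7919L * idx) %% .Machine$integer.max)

  jrows <- list()
  crows <- list()
  addj <- function(chrom, strand, start, end, count, pass) {
    if (count < 1L) return(invisible(NULL))
    jrows[[length(jrows) + 1L]] <<- data.frame(
      chrom = chrom, intron_start = as.integer(start),
      intron_end = as.integer(end), strand = strand,
      read_count = as.integer(count),
      distinct_positions = if (pass) as.integer(min(count, 40L)) else 1L,
      min_overhang = if (pass) 20L else 3L,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }

  # constitutive junctions for introns not hosting an event
  ev <- truth$events
  event_intron_keys <- character(0)
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      m <- event_member_junctions(ev[i, ])
      for (jj in m) {
        event_intron_keys <- c(event_intron_keys,
                               paste(ev$chrom[i], ev$strand[i],
                                     jj[["start"]], jj[["end"]],
                                     sep = "|"))
      }
    }
  }
  exall <- truth$exons
  for (gsp in split(exall, exall$gene_id)) {
    if (nrow(gsp) < 2L) next
    gsp <- gsp[order(gsp$start), , drop = FALSE]
    istart <- gsp$end[-nrow(gsp)]
    iend <- gsp$start[-1L]
    for (i in seq_along(istart)) {
      key <- paste(gsp$chrom[1L], gsp$strand[1L], istart[i], iend[i],
                   sep = "|")
      if (key %in% event_intron_keys) next
      cnt <- stats::rpois(1L, cfg$depth_mean)
      addj(gsp$chrom[1L], gsp$strand[1L], istart[i], iend[i], cnt,
           pass = TRUE)
    }
  }

  # event junctions and coverage
  draws <- NULL
  if (nrow(ev)) {
    p <- truth_frequencies(truth, cfg, individual_id)
    n <- stats::rpois(nrow(ev), cfg$depth_mean)
    incl <- stats::rbinom(nrow(ev), n, p)
    draws <- data.frame(key = ev$key, n = n, inclusion = incl,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(ev))) {
      m <- event_member_junctions(ev[i, ])
      pass <- !ev$fail_support[i]
      cap <- function(x) if (pass) x else min(x, 1L)
      if (ev$event_type[i] %in% c("A3SS", "A5SS")) {
        addj(ev$chrom[i], ev$strand[i], m$L[["start"]], m$L[["end"]],
             cap(incl[i]), pass)
        addj(ev$chrom[i], ev$strand[i], m$S[["start"]], m$S[["end"]],
             cap(n[i] - incl[i]), pass)
      } else if (ev$event_type[i] == "ES") {
        addj(ev$chrom[i], ev$strand[i], m$incl_up[["start"]],
             m$incl_up[["end"]], cap(incl[i]), pass)
        addj(ev$chrom[i], ev$strand[i], m$incl_down[["start"]],
             m$incl_down[["end"]], cap(incl[i]), pass)
        addj(ev$chrom[i], ev$strand[i], m$excl[["start"]],
             m$excl[["end"]], cap(n[i] - incl[i]), pass)
      } else {  # IR: spliced junction + full-length intron coverage
        addj(ev$chrom[i], ev$strand[i], ev$a1[i], ev$a2[i],
             cap(n[i] - incl[i]), pass)
        d <- cap(incl[i])
        if (d >= 1L) {
          crows[[length(crows) + 1L]] <- data.frame(
            chrom = ev$chrom[i], start = ev$a1[i], end = ev$a2[i],
            depth = as.integer(d), stringsAsFactors = FALSE)
        }
      }
    }
  }

  # decoy coverage: gap introns covered except one internal base
  if (nrow(truth$gap_introns)) {
    gi <- truth$gap_introns
    for (i in seq_len(nrow(gi))) {
      mid <- as.integer((gi$start[i] + gi$end[i]) %/% 2L)
      d <- 1L + stats::rpois(1L, 2)
      crows[[length(crows) + 1L]] <- data.frame(
        chrom = rep(gi$chrom[i], 2L),
        start = c(gi$start[i], mid + 1L),
        end = c(mid, gi$end[i]),
        depth = rep(d, 2L), stringsAsFactors = FALSE)
    }
  }

  junc <- if (length(jrows)) do.call(rbind, jrows) else
    empty_junctions()[, 1:7]
  junc <- junc[order(junc$chrom, junc$intron_start, junc$intron_end), ,
               drop = FALSE]
  cov <- if (length(crows)) do.call(rbind, crows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               depth = integer(), stringsAsFactors = FALSE)
  cov <- cov[order(cov$chrom, cov$start), , drop = FALSE]

  counts <- data.frame(
    gene_id = truth$genes$gene_id,
    individual_id = individual_id,
    count = stats::rpois(nrow(truth$genes),
                         truth$genes$true_fpkm *
                           truth$genes$exonic_length / 1000),
    stringsAsFactors = FALSE)

  jpath <- file.path(dir, paste0(individual_id, ".junctions.tsv"))
  cpath <- file.path(dir, paste0(individual_id, ".coverage.bedgraph"))
  npath <- file.path(dir, paste0(individual_id, ".counts.tsv"))
  write_junctions(junc, jpath)
  write_bedgraph(cov, cpath)
  utils::write.table(counts, npath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(junctions = jpath, coverage = cpath, counts = npath,
                 draws = draws))
}

#' Simulate a complete multi-individual study
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List with `annotation` (GFF3 path), `truth` (JSON path and
#'   the in-memory object), and named per-individual paths for
#'   `junctions`, `coverage`, `counts`.
#' @export
simulate_study <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(dir, "annotation.gff3")
  truth <- generate_genome(cfg, gff)
  paths <- lapply(cfg$individuals, function(id) {
    simulate_individual(truth, cfg, id, dir)[c("junctions", "coverage",
                                               "counts")]
  })
  names(paths) <- cfg$individuals
  tpath <- file.path(dir, "truth.json")
  write_truth(truth, tpath)
  list(annotation = gff, truth_path = tpath, truth = truth,
       junctions = vapply(paths, `[[`, "", "junctions"),
       coverage = vapply(paths, `[[`, "", "coverage"),
       counts = vapply(paths, `[[`, "", "counts"))
}

#' Write ground truth to JSON
#'
#' @param truth An `spl_truth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "spl_truth"))
  x <- unclass(truth)
  x$groups <- as.list(x$groups)  # keep individual names in JSON
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read ground truth back from JSON
#'
#' Write-then-read is the identity on the truth object.
#'
#' @param path JSON file from [write_truth()].
#' @return An `spl_truth`.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$version) || x$version != 1L) {
    stop("unsupported truth file version: ",
         if (is.null(x$version)) "none" else x$version)
  }
  x$version <- as.integer(x$version)
  x$groups <- unlist(x$groups)
  fix_df <- function(d, ints) {
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    for (cn in intersect(ints, names(d))) {
      d[[cn]] <- as.integer(d[[cn]])
    }
    d
  }
  x$genes <- fix_df(x$genes, c("n_exons", "exonic_length"))
  x$exons <- fix_df(x$exons, c("exon", "start", "end"))
  x$events <- fix_df(x$events, c("a1", "a2", "a3", "a4"))
  x$gap_introns <- fix_df(x$gap_introns, c("start", "end"))
  structure(x, class = "spl_truth")
}
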