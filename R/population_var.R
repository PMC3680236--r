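# Inter-individual splicing variation: expressed-event filtering,
# Spearman correlation of L-frequency profiles, average-linkage
# clustering, and per-event pairwise Fisher exact tests under
# Benjamini-Hochberg FDR control.

#' Population analysis settings
#'
#' @param individuals Character vector of individual IDs.
#' @param groups Named character vector mapping each individual to a
#'   group label (e.g. `southern`/`northern`). Defaults to one group.
#' @param min_fpkm Expression filter: events are analyzed only if their
#'   gene reaches this FPKM in every individual.
#' @param fdr_q Benjamini-Hochberg FDR level for flagging variable
#'   events.
#' @param exclude Individuals to drop from group testing (kept in the
#'   correlation matrix); plain configuration, e.g. for re-running a
#'   group without its most divergent members.
#' @return A list of class `spl_population_config`.
#' @export
population_config <- function(individuals,
                              groups = NULL,
                              min_fpkm = 5,
                              fdr_q = 0.05,
                              exclude = character()) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(individuals)), individuals)
  }
  if (!all(individuals %in% names(groups))) {
    stop("every individual needs a group label")
  }
  if (min_fpkm < 0) stop("min_fpkm must be >= 0")
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)")
  structure(list(individuals = individuals,
                 groups = groups[individuals],
                 min_fpkm = min_fpkm, fdr_q = fdr_q,
                 exclude = exclude),
            class = "spl_population_config")
}

#' Filter events by gene expression across all individuals
#'
#' Keeps events whose host gene has FPKM >= `min_fpkm` in every
#' individual of the configuration, excluding low-coverage genes whose
#' isoform ratios would be noise-dominated. Events not assigned to any
#' gene are dropped.
#'
#' @param events Event data frame with a `gene_id` column.
#' @param expression Data frame from [fpkm_table()].
#' @param cfg A [population_config()].
#' @return The passing subset of `events`.
#' @export
filter_expressed_events <- function(events, expression, cfg) {
  stopifnot(inherits(cfg, "spl_population_config"))
  expr <- expression[expression$individual_id %in% cfg$individuals, ,
                     drop = FALSE]
  keep_gene <- vapply(split(expr$fpkm, expr$gene_id), function(v) {
    length(v) == length(cfg$individuals) && all(v >= cfg$min_fpkm)
  }, logical(1))
  ok_genes <- names(keep_gene)[keep_gene]
  out <- events[!is.na(events$gene_id) & events$gene_id %in% ok_genes, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-isoform frequency matrix
#'
#' Reshapes a long quantification table into an events x individuals
#' matrix of L-frequencies (NA where undefined).
#'
#' @param quants Data frame from [quantify_catalog()] rows for several
#'   individuals.
#' @return Numeric matrix, rownames = event keys, colnames = individual
#'   IDs.
#' @export
l_frequency_matrix <- function(quants) {
  keys <- sort(unique(quants$key))
  inds <- unique(quants$individual_id)
  m <- matrix(NA_real_, length(keys), length(inds),
              dimnames = list(keys, inds))
  m[cbind(match(quants$key, keys),
          match(quants$individual_id, inds))] <- quants$l_frequency
  m
}

#' Pairwise Spearman correlation of L-frequency profiles
#'
#' For each pair of individuals, the rank correlation over events with a
#' defined frequency in both (pairwise-complete, mid-ranks for ties).
#' Pairs sharing fewer than two events get `NA` with a warning.
#'
#' @param lmat Matrix from [l_frequency_matrix()].
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(lmat) {
  n <- ncol(lmat)
  rho <- matrix(NA_real_, n, n,
                dimnames = list(colnames(lmat), colnames(lmat)))
  diag(rho) <- 1
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      ok <- stats::complete.cases(lmat[, c(i, k), drop = FALSE])
      if (sum(ok) < 2L) {
        warning("fewer than 2 shared events for pair ",
                colnames(lmat)[i], "/", colnames(lmat)[k])
        next
      }
      rho[i, k] <- rho[k, i] <-
        stats::cor(lmat[ok, i], lmat[ok, k], method = "spearman")
    }
  }
  rho
}

#' Average-linkage clustering of individuals
#'
#' UPGMA hierarchical clustering on the distance `1 - rho`. With the
#' deterministic input ordering of the correlation matrix, ties merge in
#' label order and merge heights are non-decreasing.
#'
#' @param cormat Complete correlation matrix from [spearman_matrix()].
#' @return An [stats::hclust] object.
#' @export
cluster_individuals <- function(cormat) {
  if (any(is.na(cormat))) {
    stop("correlation matrix has undefined entries; ",
         "filter events more strictly before clustering")
  }
  stats::hclust(stats::as.dist(1 - cormat), method = "average")
}

#' Write a dendrogram as Newick
#'
#' @param hc An [stats::hclust] object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

# vectorized two-sided Fisher exact p for 2x2 tables
# [[a, b], [c, d]]; rows = individuals, cols = long/short isoform.
# Two-sided p sums all hypergeometric outcomes no more likely than the
# observed one (with the customary (1 + 1e-7) relative tolerance).
# Degenerate tables (a zero row or column margin) get p = 1.
fisher_p_vec <- function(a, b, c, d) {
  n_t <- length(a)
  m <- a + c
  nn <- b + d
  k <- a + b
  degen <- m == 0L | nn == 0L | k == 0L | (c + d) == 0L
  lo <- pmax(0L, k - nn)
  hi <- pmin(k, m)
  len <- ifelse(degen, 0L, hi - lo + 1L)
  idx <- rep.int(seq_len(n_t), len)
  ks <- unlist(lapply(seq_len(n_t), function(i) {
    if (len[i] > 0L) lo[i]:hi[i] else integer(0)
  }), use.names = FALSE)
  p <- rep(1, n_t)
  if (length(idx)) {
    dens <- stats::dhyper(ks, m[idx], nn[idx], k[idx])
    obs <- stats::dhyper(a, m, nn, k)
    contrib <- dens * (dens <= obs[idx] * (1 + 1e-7))
    sums <- rowsum(contrib, idx)
    p[as.integer(rownames(sums))] <- pmin(1, sums[, 1L])
    p[degen] <- 1
  }
  p
}

#' Fisher exact test for one event between two individuals
#'
#' Two-sided exact test of the 2x2 table splitting junction reads by
#' individual of origin and isoform (long vs short):
#' `[[inclusion_a, exclusion_a], [inclusion_b, exclusion_b]]`.
#' Tables with a zero row or column margin are uninformative and get
#' p = 1 by convention so test denominators stay stable.
#'
#' @param inclusion_a,exclusion_a Counts in the first individual.
#' @param inclusion_b,exclusion_b Counts in the second individual.
#' @return Two-sided p-value (vectorized over the four arguments).
#' @export
fisher_event_pair <- function(inclusion_a, exclusion_a,
                              inclusion_b, exclusion_b) {
  counts <- cbind(inclusion_a, exclusion_a, inclusion_b, exclusion_b)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers")
  }
  fisher_p_vec(as.integer(inclusion_a), as.integer(exclusion_a),
               as.integer(inclusion_b), as.integer(exclusion_b))
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up adjustment (monotonicity enforced); a test is
#' flagged iff its adjusted p-value is `<= q`.
#'
#' @param pvalues Raw p-values in \[0, 1\].
#' @param q FDR level.
#' @return List with `adjusted` and logical `significant`.
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- stats::p.adjust(pvalues, method = "BH")
  list(adjusted = adjusted, significant = adjusted <= q)
}

#' Per-event pairwise Fisher tests within population groups
#'
#' For every group with >= 2 (non-excluded) individuals, tests every
#' event between every within-group pair of individuals in which the
#' event has a defined L-frequency in both members. All (event, pair)
#' tests of a group form one BH family; an event is "variable" if at
#' least one of its pairs is flagged at FDR `fdr_q`.
#'
#' Two fractions are reported per group, differing in the denominator:
#' `fraction_tested` uses the events that entered at least one test,
#' `fraction_detected` uses all events quantified in >= 1 individual of
#' the group.
#'
#' @param quants Long quantification table (rows from
#'   [quantify_catalog()] over all individuals).
#' @param cfg A [population_config()].
#' @return List of class `spl_variation`: per group a list with `tests`
#'   (data frame `key`, `ind_a`, `ind_b`, `p`, `p_adj`, `significant`),
#'   `variable_keys`, `n_events_tested`, `n_events_detected`,
#'   `fraction_tested`, `fraction_detected`.
#' @export
test_splicing_variation <- function(quants, cfg) {
  stopifnot(inherits(cfg, "spl_population_config"))
  use <- setdiff(cfg$individuals, cfg$exclude)
  out <- list()
  for (grp in unique(cfg$groups[use])) {
    members <- use[cfg$groups[use] == grp]
    if (length(members) < 2L) next
    q <- quants[quants$individual_id %in% members, , drop = FALSE]
    detected <- unique(q$key)
    defined <- q[!is.na(q$l_frequency), , drop = FALSE]
    pairs <- utils::combn(sort(members), 2L)
    tests <- vector("list", ncol(pairs))
    for (pi in seq_len(ncol(pairs))) {
      qa <- defined[defined$individual_id == pairs[1L, pi], , drop = FALSE]
      qb <- defined[defined$individual_id == pairs[2L, pi], , drop = FALSE]
      shared <- intersect(qa$key, qb$key)
      if (!length(shared)) next
      ia <- match(shared, qa$key)
      ib <- match(shared, qb$key)
      tests[[pi]] <- data.frame(
        key = shared, ind_a = pairs[1L, pi], ind_b = pairs[2L, pi],
        p = fisher_p_vec(qa$inclusion[ia], qa$exclusion[ia],
                         qb$inclusion[ib], qb$exclusion[ib]),
        stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, tests)
    if (is.null(tests)) {
      tests <- data.frame(key = character(), ind_a = character(),
                          ind_b = character(), p = numeric(),
                          p_adj = numeric(), significant = logical(),
                          stringsAsFactors = FALSE)
    } else {
      adj <- bh_adjust(tests$p, cfg$fdr_q)
      tests$p_adj <- adj$adjusted
      tests$significant <- adj$significant
    }
    variable_keys <- sort(unique(tests$key[tests$significant]))
    n_tested <- length(unique(tests$key))
    res <- list(group = grp, members = members, tests = tests,
                variable_keys = variable_keys,
                n_events_tested = n_tested,
                n_events_detected = length(detected),
                fraction_tested = if (n_tested > 0)
                  length(variable_keys) / n_tested else 0,
                fraction_detected = if (length(detected) > 0)
                  length(variable_keys) / length(detected) else 0)
    out[[grp]] <- res
  }
  class(out) <- "spl_variation"
  out
}

#' Fraction of variable events in a group
#'
#' @param variation An `spl_variation` from [test_splicing_variation()].
#' @param group Group label.
#' @param denominator `"tested"` (events that entered >= 1 test) or
#'   `"detected"` (all events quantified in the group).
#' @return Fraction in \[0, 1\].
#' @export
variable_event_fraction <- function(variation, group,
                                    denominator = c("tested", "detected")) {
  denominator <- match.arg(denominator)
  if (!group %in% names(variation)) stop("unknown group: ", group)
  if (denominator == "tested") variation[[group]]$fraction_tested
  else variation[[group]]$fraction_detected
}
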