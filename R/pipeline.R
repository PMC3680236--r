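# End-to-end orchestration: run every stage from a single configuration
# and write plain-TSV reports plus a JSON run manifest. All outputs are
# pure functions of (inputs, config); reruns are byte-identical.

#' Pipeline run configuration
#'
#' @param annotation Path to the GFF3 annotation.
#' @param junctions Named character vector: individual ID -> junction
#'   TSV path.
#' @param coverage Optional named vector of bedGraph paths (same names);
#'   without it intron retention is skipped.
#' @param counts Path to the fragment-count TSV (all individuals).
#' @param groups Named character vector: individual -> group label.
#' @param filter A [filter_config()].
#' @param min_fpkm,fdr_q Population-analysis settings (see
#'   [population_config()]).
#' @param exclude Individuals excluded from group testing.
#' @param k_high Conservation threshold ("in >= k individuals").
#' @param out_dir Report directory (created by [run_all()]).
#' @param seed Seed for any stochastic step.
#' @return A list of class `spl_run_config`.
#' @export
run_config <- function(annotation, junctions, coverage = NULL, counts,
                       groups = NULL, filter = filter_config(),
                       min_fpkm = 5, fdr_q = 0.05,
                       exclude = character(), k_high = 15L,
                       out_dir = "splicescape_out", seed = 1L) {
  inds <- names(junctions)
  if (is.null(inds) || any(!nzchar(inds))) {
    stop("junctions must be a named vector (individual -> path)")
  }
  for (p in c(annotation, unname(junctions), unname(coverage), counts)) {
    if (!file.exists(p)) stop("input file missing: ", p)
  }
  if (!is.null(coverage) && !all(inds %in% names(coverage))) {
    stop("coverage missing for individual(s): ",
         paste(setdiff(inds, names(coverage)), collapse = ", "))
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(inds)), inds)
  }
  structure(list(annotation = annotation, junctions = junctions,
                 coverage = coverage, counts = counts,
                 groups = groups[inds], filter = filter,
                 min_fpkm = min_fpkm, fdr_q = fdr_q, exclude = exclude,
                 k_high = as.integer(k_high), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "spl_run_config")
}

#' Load a run configuration from YAML
#'
#' Mirrors the arguments of [run_config()]; `junctions`, `coverage` and
#' `groups` are given as mappings from individual ID to path/label.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A `spl_run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  filt <- do.call(filter_config, as.list(y$filter %||% list()))
  run_config(
    annotation = resolve(y$annotation),
    junctions = stats::setNames(resolve(unlist(y$junctions)),
                                names(y$junctions)),
    coverage = if (!is.null(y$coverage))
      stats::setNames(resolve(unlist(y$coverage)), names(y$coverage)),
    counts = resolve(y$counts),
    groups = if (!is.null(y$groups)) unlist(y$groups),
    filter = filt,
    min_fpkm = y$min_fpkm %||% 5,
    fdr_q = y$fdr_q %||% 0.05,
    exclude = unlist(y$exclude %||% character()),
    k_high = y$k_high %||% 15L,
    out_dir = y$out_dir %||% "splicescape_out",
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Stages: load annotation; read, filter and label junctions per
#' individual; FPKM table and expression categories; per-individual
#' event catalogs; cross-individual conservation summary; isoform
#' quantification; expression-filtered population variation analysis
#' (Spearman matrix, average-linkage dendrogram, pairwise Fisher tests
#' with BH flags). Reports are written as TSV/Newick/JSON into
#' `cfg$out_dir`; a manifest records the package version, a hash of the
#' configuration, and per-report row counts.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "spl_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  inds <- names(cfg$junctions)

  ann <- load_annotation(cfg$annotation)

  raw <- lapply(inds, function(id) {
    read_junctions(cfg$junctions[[id]], "tsv", individual_id = id)
  })
  names(raw) <- inds
  filtered <- lapply(raw, filter_junctions, cfg = cfg$filter)
  labelled <- lapply(filtered, classify_known_novel, annotation = ann)
  jsum <- data.frame(
    individual_id = inds,
    n_junctions = vapply(raw, nrow, integer(1)),
    n_pass = vapply(filtered, nrow, integer(1)),
    n_known = vapply(labelled, function(j) sum(j$status == "known"),
                     integer(1)),
    n_novel = vapply(labelled, function(j) sum(j$status == "novel"),
                     integer(1)),
    stringsAsFactors = FALSE)
  write_tsv(jsum, file.path(cfg$out_dir, "junction_summary.tsv"))
  shar <- junction_sharing_histogram(filtered, ann)
  write_tsv(shar, file.path(cfg$out_dir, "junction_sharing.tsv"))

  counts <- read_fragment_counts(cfg$counts)
  expr <- fpkm_table(counts, ann)
  write_tsv(expr, file.path(cfg$out_dir, "fpkm.tsv"))
  cats <- as.data.frame.matrix(
    table(expr$individual_id, expr$category))
  cats <- cbind(individual_id = rownames(cats), cats,
                stringsAsFactors = FALSE)
  rownames(cats) <- NULL
  write_tsv(cats, file.path(cfg$out_dir, "expression_categories.tsv"))

  covs <- lapply(inds, function(id) {
    if (is.null(cfg$coverage)) NULL else read_bedgraph(cfg$coverage[[id]])
  })
  names(covs) <- inds
  catalogs <- lapply(inds, function(id) {
    build_catalog(id, filtered[[id]], covs[[id]], ann)
  })
  names(catalogs) <- inds
  allev <- do.call(rbind, lapply(catalogs, function(cc) {
    if (!nrow(cc$events)) return(NULL)
    cbind(individual_id = cc$individual_id, cc$events,
          stringsAsFactors = FALSE)
  }))
  if (is.null(allev)) {
    allev <- cbind(individual_id = character(0), empty_events(),
                   gene_id = character(0))
  }
  write_tsv(allev, file.path(cfg$out_dir, "events.tsv"))
  csum <- data.frame(
    individual_id = inds,
    as_genes = vapply(catalogs, function(cc) cc$n_as_genes, integer(1)),
    A3SS = vapply(catalogs, function(cc) cc$type_counts[["A3SS"]],
                  integer(1)),
    A5SS = vapply(catalogs, function(cc) cc$type_counts[["A5SS"]],
                  integer(1)),
    IR = vapply(catalogs, function(cc) cc$type_counts[["IR"]],
                integer(1)),
    ES = vapply(catalogs, function(cc) cc$type_counts[["ES"]],
                integer(1)),
    stringsAsFactors = FALSE)
  write_tsv(csum, file.path(cfg$out_dir, "catalog_summary.tsv"))

  cons <- presence_and_conservation(catalogs, k_high = cfg$k_high)
  consout <- cons$summary
  num <- vapply(consout, is.numeric, logical(1))
  consout[num] <- lapply(consout[num], function(v) round(v, 4))
  write_tsv(consout, file.path(cfg$out_dir, "conservation_summary.tsv"))

  quants <- do.call(rbind, lapply(inds, function(id) {
    quantify_catalog(catalogs[[id]], filtered[[id]], covs[[id]])
  }))
  write_tsv(quants, file.path(cfg$out_dir, "quantifications.tsv"))

  pop <- population_config(inds, cfg$groups, min_fpkm = cfg$min_fpkm,
                           fdr_q = cfg$fdr_q, exclude = cfg$exclude)
  expressed <- filter_expressed_events(
    allev[!duplicated(allev$key), , drop = FALSE], expr, pop)
  qexp <- quants[quants$key %in% expressed$key, , drop = FALSE]
  lmat <- l_frequency_matrix(qexp)
  variation <- NULL
  if (nrow(lmat) >= 2L && length(inds) >= 2L) {
    rho <- spearman_matrix(lmat)
    rout <- cbind(individual_id = rownames(rho),
                  as.data.frame(round(rho, 6)))
    write_tsv(rout, file.path(cfg$out_dir, "correlation_matrix.tsv"))
    if (!any(is.na(rho))) {
      hc <- cluster_individuals(rho)
      write_dendrogram_newick(hc, file.path(cfg$out_dir,
                                            "dendrogram.nwk"))
    }
    variation <- test_splicing_variation(qexp, pop)
    tests <- do.call(rbind, lapply(variation, function(g) {
      if (!nrow(g$tests)) return(NULL)
      cbind(group = g$group, g$tests, stringsAsFactors = FALSE)
    }))
    if (!is.null(tests)) {
      tests$p <- signif(tests$p, 8)
      tests$p_adj <- signif(tests$p_adj, 8)
      write_tsv(tests, file.path(cfg$out_dir, "variation_tests.tsv"))
    }
    vsum <- data.frame(
      group = names(variation),
      n_events_tested = vapply(variation, function(g) g$n_events_tested,
                               integer(1)),
      n_events_detected = vapply(variation,
                                 function(g) g$n_events_detected,
                                 integer(1)),
      n_variable = vapply(variation,
                          function(g) length(g$variable_keys),
                          integer(1)),
      fraction_tested = round(vapply(variation,
                                     function(g) g$fraction_tested,
                                     numeric(1)), 6),
      fraction_detected = round(vapply(variation,
                                       function(g) g$fraction_detected,
                                       numeric(1)), 6),
      stringsAsFactors = FALSE)
    write_tsv(vsum, file.path(cfg$out_dir, "variation_summary.tsv"))
  }

  manifest <- list(
    package = "splicescape",
    version = as.character(utils::packageVersion("splicescape")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_individuals = length(inds),
    n_genes = nrow(ann$genes),
    rows = list(events = nrow(allev), quantifications = nrow(quants),
                fpkm = nrow(expr)))
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(annotation = ann, junctions = filtered,
                 expression = expr, catalogs = catalogs,
                 conservation = cons, quantifications = quants,
                 variation = variation, manifest = manifest))
}

# md5 of the canonical JSON serialization of the analysis parameters
# (the output location does not affect the hash)
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}
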