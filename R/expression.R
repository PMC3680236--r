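# Gene expression summaries: FPKM, expression categories, and
# feature-class read-density summaries from per-base coverage.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' `fpkm = fragment_count / (exonic_length/1000) / (total_mapped/1e6)`.
#' The exonic length is the collapsed exon union of the gene, so FPKM is
#' a per-gene (not per-transcript) quantity. Counts are fragments: a read
#' pair counts once.
#'
#' @param fragment_count Non-negative fragment count(s).
#' @param exonic_length Collapsed exonic length(s), bp; must be > 0.
#' @param total_mapped_fragments Library total; must be > 0.
#' @return Numeric FPKM, vectorized over the arguments.
#' @examples
#' compute_fpkm(100, 1000, 1e6)  # 100
#' @export
compute_fpkm <- function(fragment_count, exonic_length,
                         total_mapped_fragments) {
  if (any(exonic_length <= 0)) stop("exonic_length must be positive")
  if (any(total_mapped_fragments <= 0)) {
    stop("total_mapped_fragments must be positive")
  }
  if (any(fragment_count < 0)) stop("fragment_count must be non-negative")
  fragment_count / (exonic_length / 1000) / (total_mapped_fragments / 1e6)
}

#' Categorize an FPKM value
#'
#' `zero` (FPKM = 0, no coverage), `low` (0 < FPKM < low), `medium`
#' (low <= FPKM <= high), `high` (FPKM > high). The default boundaries
#' put FPKM 5 and 40 in the medium class.
#'
#' @param fpkm Non-negative FPKM value(s).
#' @param low Lower boundary of the medium class (inclusive).
#' @param high Upper boundary of the medium class (inclusive).
#' @return Factor with levels `zero`, `low`, `medium`, `high`.
#' @export
categorize_expression <- function(fpkm, low = 5, high = 40) {
  if (any(is.na(fpkm)) || any(fpkm < 0)) {
    stop("fpkm must be non-negative and non-missing")
  }
  out <- ifelse(fpkm == 0, "zero",
                ifelse(fpkm < low, "low",
                       ifelse(fpkm <= high, "medium", "high")))
  factor(out, levels = c("zero", "low", "medium", "high"))
}

#' Read a per-gene fragment-count table
#'
#' Tab-separated with header `gene_id individual_id count`.
#'
#' @param path Input TSV.
#' @return Data frame with those three columns.
#' @export
read_fragment_counts <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("gene_id", "individual_id", "count")
  if (!all(need %in% names(d))) {
    stop("fragment-count table must have columns: ",
         paste(need, collapse = ", "))
  }
  if (any(d$count < 0)) stop("negative fragment count in ", path)
  d[, need]
}

#' Per-gene, per-individual expression table
#'
#' Joins fragment counts with collapsed exonic lengths and computes FPKM
#' and the expression category for every (gene, individual). The library
#' total defaults to the per-individual sum of counts over the table.
#'
#' @param counts Data frame from [read_fragment_counts()].
#' @param annotation An `spl_annotation`.
#' @param total_mapped Optional named vector of per-individual library
#'   totals (fragments). Defaults to per-individual column sums.
#' @param low,high Category boundaries passed to
#'   [categorize_expression()].
#' @return Data frame: `gene_id`, `individual_id`, `fragment_count`,
#'   `fpkm`, `category`.
#' @export
fpkm_table <- function(counts, annotation, total_mapped = NULL,
                       low = 5, high = 40) {
  stopifnot(inherits(annotation, "spl_annotation"))
  len <- stats::setNames(annotation$genes$collapsed_length,
                         annotation$genes$gene_id)
  unknown <- !(counts$gene_id %in% names(len))
  if (any(unknown)) {
    warning(sum(unknown), " count row(s) for genes absent from the ",
            "annotation dropped")
    counts <- counts[!unknown, , drop = FALSE]
  }
  if (is.null(total_mapped)) {
    total_mapped <- tapply(counts$count, counts$individual_id, sum)
  }
  tm <- total_mapped[counts$individual_id]
  fpkm <- compute_fpkm(counts$count, len[counts$gene_id], tm)
  data.frame(gene_id = counts$gene_id,
             individual_id = counts$individual_id,
             fragment_count = counts$count,
             fpkm = as.numeric(fpkm),
             category = categorize_expression(fpkm, low, high),
             stringsAsFactors = FALSE)
}

#' Top expressed genes by mean FPKM
#'
#' Genes ranked by mean FPKM across individuals, descending; ties broken
#' lexicographically by `gene_id`.
#'
#' @param expression Data frame from [fpkm_table()].
#' @param n Number of genes to return (all if fewer exist).
#' @return Data frame `gene_id`, `mean_fpkm`, ranked.
#' @export
top_expressed <- function(expression, n = 100L) {
  if (!nrow(expression)) stop("empty expression table")
  m <- tapply(expression$fpkm, expression$gene_id, mean)
  d <- data.frame(gene_id = names(m), mean_fpkm = as.numeric(m),
                  stringsAsFactors = FALSE)
  d <- d[order(-d$mean_fpkm, d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  utils::head(d, n)
}

#' Read a bedGraph coverage track
#'
#' @param path bedGraph file (4 columns, 0-based half-open intervals).
#' @return Data frame `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = as.numeric(gr$score),
             stringsAsFactors = FALSE)
}

#' Write a coverage data frame as bedGraph
#'
#' @param coverage Data frame `chrom`, `start`, `end`, `depth`.
#' @param path Output path.
#' @export
write_bedgraph <- function(coverage, path) {
  utils::write.table(coverage[, c("chrom", "start", "end", "depth")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read-density summary over exon / intron / intergenic classes
#'
#' Assigns every base of the genome universe to exactly one class with
#' precedence exon > intron > intergenic (a base inside any gene's
#' collapsed exons is exonic; a base inside an annotated intron and not
#' exonic is intronic; everything else is intergenic). The universe per
#' chromosome spans from 0 to the furthest annotated or covered base.
#' Densities are depth-based FPKM-style values: summed per-base depth of
#' the class, per kilobase of class length, per million units of total
#' depth.
#'
#' @param coverage Data frame from [read_bedgraph()].
#' @param annotation An `spl_annotation`.
#' @return List with `class_length` (bp per class), `depth_sum`,
#'   `fraction` (share of total depth; sums to 1), and `density`.
#' @export
feature_density_summary <- function(coverage, annotation) {
  stopifnot(inherits(annotation, "spl_annotation"))
  chroms <- unique(c(annotation$genes$chrom, coverage$chrom))
  unknown <- setdiff(unique(coverage$chrom), annotation$genes$chrom)
  if (length(unknown) && nrow(annotation$genes)) {
    warning("coverage on chromosome(s) without annotation: ",
            paste(unknown, collapse = ", "))
  }
  classes <- c("exon", "intron", "intergenic")
  len <- depth <- stats::setNames(numeric(3), classes)
  for (ch in chroms) {
    cov <- coverage[coverage$chrom == ch, , drop = FALSE]
    exo <- annotation$collapsed[annotation$collapsed$chrom == ch, ,
                                drop = FALSE]
    intr <- annotation$introns[annotation$introns$chrom == ch, ,
                               drop = FALSE]
    hi <- max(c(exo$end, intr$end, cov$end, 0L))
    if (hi == 0L) next
    universe <- IRanges::IRanges(1L, hi)
    exon_r <- IRanges::reduce(IRanges::IRanges(exo$start + 1L, exo$end))
    intron_r <- IRanges::setdiff(
      IRanges::reduce(IRanges::IRanges(intr$start + 1L, intr$end)), exon_r)
    inter_r <- IRanges::setdiff(IRanges::setdiff(universe, exon_r),
                                intron_r)
    rs <- list(exon = exon_r, intron = intron_r, intergenic = inter_r)
    cov_r <- IRanges::IRanges(cov$start + 1L, cov$end)
    for (cl in classes) {
      len[cl] <- len[cl] + sum(IRanges::width(rs[[cl]]))
      if (!nrow(cov)) next
      ov <- IRanges::findOverlaps(cov_r, rs[[cl]])
      if (!length(ov)) next
      inter <- IRanges::pintersect(
        cov_r[S4Vectors::queryHits(ov)], rs[[cl]][S4Vectors::subjectHits(ov)])
      depth[cl] <- depth[cl] +
        sum(IRanges::width(inter) * cov$depth[S4Vectors::queryHits(ov)])
    }
  }
  total <- sum(depth)
  fraction <- if (total > 0) depth / total else depth * 0
  density <- ifelse(len > 0 & total > 0,
                    depth / (len / 1000) / (total / 1e6), 0)
  list(class_length = len, depth_sum = depth, fraction = fraction,
       density = density)
}
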