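# Gene-model handling: GFF3 loading, intron derivation, collapsed exon unions.
#
# Internal coordinate convention: 0-based half-open intervals [start, end).
# GFF3 (1-based closed) is converted at the I/O boundary and nowhere else.

#' Load gene annotation from a GFF3 file
#'
#' Reads a gene/mRNA/exon feature hierarchy (linked through `Parent`
#' attributes) and builds the annotation object used throughout the
#' pipeline: per-transcript exon tables, per-transcript introns
#' (deduplicated across transcripts by coordinates), and the collapsed
#' exon union of each gene.
#'
#' Coordinates are converted to 0-based half-open intervals on load.
#' Genes without any transcript or exon are dropped with a warning, as are
#' exons whose `Parent` transcript is unknown.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return An object of class `spl_annotation`: a list with elements
#'   `genes` (data frame: `gene_id`, `chrom`, `strand`, `span_start`,
#'   `span_end`, `collapsed_length`), `exons` (data frame: `gene_id`,
#'   `transcript_id`, `chrom`, `strand`, `start`, `end`, `internal`),
#'   `introns` (data frame: `chrom`, `strand`, `start`, `end`, `gene_id`,
#'   `annotated`; unique by coordinates), and `collapsed` (data frame of
#'   merged exon intervals per gene).
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t1\t900\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tmRNA\t1\t900\t.\t+\t.\tID=g1.1;Parent=g1",
#'   "chr1\tsrc\texon\t1\t100\t.\t+\t.\tParent=g1.1",
#'   "chr1\tsrc\texon\t201\t300\t.\t+\t.\tParent=g1.1",
#'   "chr1\tsrc\texon\t401\t900\t.\t+\t.\tParent=g1.1"), gff)
#' ann <- load_annotation(gff)
#' ann$genes
#' @export
load_annotation <- function(gff3_path) {
  if (!file.exists(gff3_path)) {
    stop("annotation file not found: ", gff3_path)
  }
  gr <- tryCatch(
    rtracklayer::import(gff3_path, format = "gff3"),
    error = function(e) {
      stop("malformed GFF3 '", gff3_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  feat <- as.character(gr$type)
  first_parent <- function(p) {
    vapply(p, function(x) if (length(x)) x[[1]] else NA_character_,
           character(1))
  }

  is_gene <- feat == "gene"
  is_tx   <- feat %in% c("mRNA", "transcript")
  is_exon <- feat == "exon"

  gene_ids <- as.character(gr$ID[is_gene])
  tx_ids <- as.character(gr$ID[is_tx])
  tx_parent <- first_parent(gr$Parent[is_tx])
  tx2gene <- stats::setNames(tx_parent, tx_ids)

  if (!any(is_gene)) {
    warning("no gene features found in ", gff3_path)
    return(empty_annotation())
  }

  exon_parent <- gr$Parent[is_exon]
  exon_n <- lengths(exon_parent)
  orphan <- exon_n == 0L
  if (any(orphan)) {
    warning(sum(orphan), " exon feature(s) without Parent skipped")
  }
  # exons may list several parent transcripts; expand one row per parent
  keep <- which(is_exon)[!orphan]
  parents <- gr$Parent[keep]
  rep_idx <- rep.int(keep, lengths(parents))
  exons <- data.frame(
    transcript_id = unlist(parents, use.names = FALSE),
    chrom  = as.character(GenomicRanges::seqnames(gr))[rep_idx],
    strand = as.character(GenomicRanges::strand(gr))[rep_idx],
    start  = GenomicRanges::start(gr)[rep_idx] - 1L,
    end    = GenomicRanges::end(gr)[rep_idx],
    stringsAsFactors = FALSE
  )
  known_tx <- exons$transcript_id %in% tx_ids
  if (any(!known_tx)) {
    warning(sum(!known_tx), " exon(s) with unknown Parent transcript skipped")
    exons <- exons[known_tx, , drop = FALSE]
  }
  exons$gene_id <- unname(tx2gene[exons$transcript_id])
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
  rownames(exons) <- NULL

  present <- gene_ids %in% exons$gene_id
  if (any(!present)) {
    warning(sum(!present), " gene(s) without exons dropped")
  }
  gene_ids <- sort(gene_ids[present])
  if (!length(gene_ids)) {
    warning("annotation contains no usable genes")
    return(empty_annotation())
  }
  exons <- exons[exons$gene_id %in% gene_ids, , drop = FALSE]

  # flag internal exons (neither first nor last within their transcript)
  exons$internal <- internal_flag(exons)

  collapsed <- collapse_exons(exons)
  cl <- tapply(collapsed$end - collapsed$start, collapsed$gene_id, sum)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = exons$chrom[match(gene_ids, exons$gene_id)],
    strand = exons$strand[match(gene_ids, exons$gene_id)],
    span_start = as.integer(tapply(exons$start, exons$gene_id, min)[gene_ids]),
    span_end = as.integer(tapply(exons$end, exons$gene_id, max)[gene_ids]),
    collapsed_length = as.integer(cl[gene_ids]),
    stringsAsFactors = FALSE
  )
  rownames(genes) <- NULL

  introns <- introns_from_exons(exons)

  ann <- structure(
    list(genes = genes, exons = exons, introns = introns,
         collapsed = collapsed),
    class = "spl_annotation"
  )
  message("loaded ", nrow(genes), " gene(s), ",
          length(unique(exons$transcript_id)), " transcript(s), ",
          nrow(introns), " distinct intron(s) from ", gff3_path)
  ann
}

empty_annotation <- function() {
  structure(list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       strand = character(), span_start = integer(),
                       span_end = integer(), collapsed_length = integer(),
                       stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = character(), chrom = character(),
                       strand = character(), start = integer(),
                       end = integer(), gene_id = character(),
                       internal = logical(), stringsAsFactors = FALSE),
    introns = data.frame(chrom = character(), strand = character(),
                         start = integer(), end = integer(),
                         gene_id = character(), annotated = logical(),
                         stringsAsFactors = FALSE),
    collapsed = data.frame(gene_id = character(), chrom = character(),
                           strand = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)
  ), class = "spl_annotation")
}

internal_flag <- function(exons) {
  flag <- logical(nrow(exons))
  for (idx in split(seq_len(nrow(exons)), exons$transcript_id)) {
    if (length(idx) > 2L) {
      ord <- idx[order(exons$start[idx])]
      flag[ord[-c(1L, length(ord))]] <- TRUE
    }
  }
  flag
}

collapse_exons <- function(exons) {
  out <- lapply(split(exons, exons$gene_id), function(e) {
    red <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

introns_from_exons <- function(exons) {
  res <- lapply(split(exons, exons$transcript_id), function(e) {
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) return(NULL)
    if (any(e$start[-1L] < e$end[-nrow(e)])) {
      stop("overlapping exons within transcript ", e$transcript_id[1L])
    }
    data.frame(chrom = e$chrom[1L], strand = e$strand[1L],
               start = e$end[-nrow(e)], end = e$start[-1L],
               gene_id = e$gene_id[1L], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), stringsAsFactors = FALSE)
  }
  # deduplicate across transcripts by coordinates
  key <- paste(res$chrom, res$strand, res$start, res$end, sep = "|")
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$chrom, res$start, res$end), , drop = FALSE]
  res$annotated <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}

#' Extract one gene model from an annotation
#'
#' @param annotation An `spl_annotation` from [load_annotation()].
#' @param gene_id Gene identifier.
#' @return An object of class `spl_gene`: a list with `gene_id`, `chrom`,
#'   `strand`, `transcripts` (named list of exon data frames, sorted by
#'   start), `collapsed_exons` (merged exon intervals) and
#'   `collapsed_length`.
#' @export
gene_model <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "spl_annotation"))
  e <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(e)) stop("unknown gene_id: ", gene_id)
  txs <- lapply(split(e, e$transcript_id), function(t) {
    t <- t[order(t$start), c("start", "end")]
    rownames(t) <- NULL
    t
  })
  coll <- annotation$collapsed[
    annotation$collapsed$gene_id == gene_id, , drop = FALSE]
  structure(list(
    gene_id = gene_id, chrom = e$chrom[1L], strand = e$strand[1L],
    transcripts = txs,
    collapsed_exons = coll[, c("start", "end")],
    collapsed_length = sum(coll$end - coll$start)
  ), class = "spl_gene")
}

#' Derive introns of a gene model
#'
#' Introns are the gaps between adjacent exons of each transcript,
#' deduplicated across transcripts by (chrom, strand, start, end) —
#' intron-retention events are per-intron, not per-transcript.
#'
#' @param gene An `spl_gene` from [gene_model()].
#' @return Data frame with `chrom`, `strand`, `start`, `end`, `gene_id`,
#'   `annotated`. Zero rows for single-exon genes.
#' @export
derive_introns <- function(gene) {
  stopifnot(inherits(gene, "spl_gene"))
  rows <- lapply(gene$transcripts, function(t) {
    if (nrow(t) < 2L) return(NULL)
    if (any(t$start[-1L] < t$end[-nrow(t)])) {
      stop("overlapping exons within a transcript of gene ", gene$gene_id)
    }
    data.frame(chrom = gene$chrom, strand = gene$strand,
               start = t$end[-nrow(t)], end = t$start[-1L],
               gene_id = gene$gene_id, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      gene_id = character(), annotated = logical(),
                      stringsAsFactors = FALSE))
  }
  if (any(res$end <= res$start)) {
    stop("zero-length intron in gene ", gene$gene_id)
  }
  key <- paste(res$chrom, res$strand, res$start, res$end, sep = "|")
  res <- res[!duplicated(key), , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  res$annotated <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}

#' Collapsed exonic length of a gene
#'
#' Measure of the union of all exon intervals across transcripts, in base
#' pairs. This is the exonic length used as the FPKM denominator, so
#' duplicated or overlapping exons across transcripts are counted once.
#'
#' @param gene An `spl_gene` from [gene_model()].
#' @return Integer base-pair count.
#' @export
collapsed_exon_length <- function(gene) {
  stopifnot(inherits(gene, "spl_gene"))
  as.integer(sum(gene$collapsed_exons$end - gene$collapsed_exons$start))
}

#' @export
print.spl_annotation <- function(x, ...) {
  cat("spl_annotation:", nrow(x$genes), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$introns), "distinct introns\n")
  invisible(x)
}
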