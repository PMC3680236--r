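# Splice-junction evidence: I/O, support filtering, known/novel labelling,
# cross-individual sharing histograms.
#
# A junction record describes the intron interval removed by splicing,
# 0-based half-open, together with its read support in one individual:
# total junction-spanning reads, distinct alignment start positions among
# them, and the smaller of the maximal left/right anchor overhangs.

#' Junction support filter settings
#'
#' Defaults encode the support rule used throughout: a junction must be
#' backed by at least two reads, at non-repetitive (>= 2 distinct)
#' alignment positions, anchored by at least 4 bases on both sides.
#'
#' @param min_reads Minimum junction-spanning read count.
#' @param min_distinct_positions Minimum distinct alignment start
#'   positions among supporting reads (guards against PCR/mapping
#'   duplicates).
#' @param min_overhang Minimum anchor overhang in bases on both sides.
#' @return A list of class `spl_filter_config`.
#' @export
filter_config <- function(min_reads = 2L, min_distinct_positions = 2L,
                          min_overhang = 4L) {
  cfg <- list(min_reads = as.integer(min_reads),
              min_distinct_positions = as.integer(min_distinct_positions),
              min_overhang = as.integer(min_overhang))
  if (any(vapply(cfg, function(v) is.na(v) || v < 1L, logical(1)))) {
    stop("all filter thresholds must be >= 1")
  }
  class(cfg) <- "spl_filter_config"
  cfg
}

junction_key <- function(j) {
  paste(j$chrom, j$strand, j$intron_start, j$intron_end, sep = "|")
}

empty_junctions <- function() {
  data.frame(chrom = character(), strand = character(),
             intron_start = integer(), intron_end = integer(),
             read_count = integer(), distinct_positions = integer(),
             min_overhang = integer(), individual_id = character(),
             stringsAsFactors = FALSE)
}

#' Read per-individual junction evidence
#'
#' Two dialects are supported. `"tsv"`: a 7-column tab-separated table
#' with header `chrom intron_start intron_end strand read_count
#' distinct_positions min_overhang`, intron interval 0-based half-open.
#' `"bed12"`: TopHat-style junction BED where each record carries two
#' blocks; the intron is the gap between the blocks, the score column is
#' the read count, and the overhang is the smaller block size (distinct
#' positions are not recorded in BED12 and default to the read count).
#'
#' @param path Input file.
#' @param dialect `"tsv"` or `"bed12"`.
#' @param individual_id Identifier stored on every record.
#' @return Data frame of junction evidence (one row per junction).
#' @export
read_junctions <- function(path, dialect = c("tsv", "bed12"),
                           individual_id = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("junction file not found: ", path)
  j <- switch(dialect,
              tsv = read_junctions_tsv(path),
              bed12 = read_junctions_bed12(path))
  j$individual_id <- rep(individual_id, nrow(j))
  bad <- which(j$intron_end <= j$intron_start)
  if (length(bad)) {
    stop("junction with end <= start at ", path, " record ", bad[1L])
  }
  bad <- which(j$read_count < 0L | j$distinct_positions < 0L |
                 j$min_overhang < 0L)
  if (length(bad)) {
    stop("negative count at ", path, " record ", bad[1L])
  }
  bad <- which(j$distinct_positions > j$read_count)
  if (length(bad)) {
    stop("distinct_positions exceeds read_count at ", path,
         " record ", bad[1L])
  }
  j
}

read_junctions_tsv <- function(path) {
  cols <- c("chrom", "intron_start", "intron_end", "strand", "read_count",
            "distinct_positions", "min_overhang")
  first <- readLines(path, n = 1L)
  if (!length(first)) return(empty_junctions())
  has_header <- grepl("chrom", first, fixed = TRUE)
  d <- utils::read.table(path, sep = "\t", header = has_header,
                         stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "integer", "integer",
                                        "integer"))
  if (ncol(d) != 7L) stop("expected 7 columns in junction TSV ", path)
  names(d) <- cols
  d
}

read_junctions_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (!length(lines)) return(empty_junctions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rows <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    if (length(f) < 12L) {
      stop("BED12 record with <12 fields at ", path, " line ", i)
    }
    sizes <- as.integer(strsplit(f[11L], ",")[[1]])
    starts <- as.integer(strsplit(f[12L], ",")[[1]])
    if (length(sizes) != 2L) {
      stop("expected 2 blocks in junction BED12 at ", path, " line ", i)
    }
    chrom_start <- as.integer(f[2L])
    data.frame(chrom = f[1L], strand = f[6L],
               intron_start = chrom_start + starts[1L] + sizes[1L],
               intron_end = chrom_start + starts[2L],
               read_count = as.integer(f[5L]),
               distinct_positions = as.integer(f[5L]),
               min_overhang = min(sizes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write junction evidence in the TSV dialect
#'
#' @param junctions Junction data frame.
#' @param path Output path.
#' @export
write_junctions <- function(junctions, path) {
  cols <- c("chrom", "intron_start", "intron_end", "strand", "read_count",
            "distinct_positions", "min_overhang")
  utils::write.table(junctions[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply the junction support filter
#'
#' A junction passes iff `read_count >= min_reads` AND
#' `distinct_positions >= min_distinct_positions` AND
#' `min_overhang >= min_overhang`. Filtering is monotone: tightening any
#' threshold can only shrink the passing set.
#'
#' @param junctions Junction data frame from [read_junctions()].
#' @param cfg A [filter_config()].
#' @return The passing subset.
#' @export
filter_junctions <- function(junctions, cfg = filter_config()) {
  stopifnot(inherits(cfg, "spl_filter_config"))
  pass <- junctions$read_count >= cfg$min_reads &
    junctions$distinct_positions >= cfg$min_distinct_positions &
    junctions$min_overhang >= cfg$min_overhang
  message("junction filter: ", sum(pass), " passing / ",
          sum(!pass), " failing")
  out <- junctions[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label junctions as known or novel against the annotation
#'
#' A junction is `known` iff its (chrom, strand, intron_start, intron_end)
#' exactly matches an annotated intron; any coordinate or strand
#' difference makes it `novel`.
#'
#' @param junctions Junction data frame.
#' @param annotation An `spl_annotation`.
#' @return `junctions` with an added `status` column (`known`/`novel`).
#' @export
classify_known_novel <- function(junctions, annotation) {
  stopifnot(inherits(annotation, "spl_annotation"))
  ikey <- paste(annotation$introns$chrom, annotation$introns$strand,
                annotation$introns$start, annotation$introns$end,
                sep = "|")
  known <- junction_key(junctions) %in% ikey
  junctions$status <- ifelse(known, "known", "novel")
  message("junction status: ", sum(known), " known, ",
          sum(!known), " novel")
  junctions
}

#' Junction sharing across individuals
#'
#' Counts, for each k, the distinct junctions observed in exactly k of
#' the N individuals, optionally split into known and novel against an
#' annotation.
#'
#' @param junctions_by_individual Named list of junction data frames
#'   (one per individual; usually the filtered sets).
#' @param annotation Optional `spl_annotation` for the known/novel split.
#' @return Data frame with `n_individuals`, `known`, `novel`, `total`
#'   (the `known`/`novel` columns are `NA` without an annotation). Column
#'   `total` sums to the number of distinct junction keys.
#' @export
junction_sharing_histogram <- function(junctions_by_individual,
                                       annotation = NULL) {
  n <- length(junctions_by_individual)
  if (n < 1L) stop("need at least one individual")
  keysets <- lapply(junctions_by_individual,
                    function(j) unique(junction_key(j)))
  all_keys <- unlist(keysets, use.names = FALSE)
  if (!length(all_keys)) {
    return(data.frame(n_individuals = integer(), known = integer(),
                      novel = integer(), total = integer()))
  }
  counts <- table(all_keys)
  status <- NULL
  if (!is.null(annotation)) {
    ikey <- paste(annotation$introns$chrom, annotation$introns$strand,
                  annotation$introns$start, annotation$introns$end,
                  sep = "|")
    status <- ifelse(names(counts) %in% ikey, "known", "novel")
  }
  ks <- seq_len(n)
  known <- novel <- rep(NA_integer_, n)
  total <- vapply(ks, function(k) sum(counts == k), integer(1))
  if (!is.null(status)) {
    known <- vapply(ks, function(k) sum(counts == k & status == "known"),
                    integer(1))
    novel <- total - known
  }
  data.frame(n_individuals = ks, known = known, novel = novel,
             total = total)
}
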