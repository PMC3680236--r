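# Two-isoform quantification of AS events from junction read counts and
# coverage: inclusion/exclusion counts and the Isoform(L) frequency.
#
# The long (L) isoform is the inclusion isoform of each event:
#   IR         the intron-retained form
#   ES         the exon-included form
#   A3SS/A5SS  the member junction producing the longer mature
#              transcript, i.e. the one removing the shorter intron.
#
# Counting rules (integers, so they can enter Fisher 2x2 tables):
#   A3SS/A5SS  inclusion = reads on the L junction,
#              exclusion = reads on the S junction
#   ES         inclusion = floor(mean of the two inclusion-junction read
#              counts), exclusion = exclusion-junction reads
#   IR         inclusion = floor(mean coverage depth at the two
#              exon-intron boundary bases, i.e. the first and last intron
#              bases), exclusion = spliced-junction reads. Boundary depth
#              (rather than intron-body FPKM) keeps inclusion and
#              exclusion commensurate junction-like counts: intron-body
#              totals grow with intron length and would bias the 2x2 test.

# member junction intervals (intron removed) of an event, as a list of
# (start, end) rows; L first, S second; NULL for IR
event_member_junctions <- function(event) {
  type <- event$event_type
  if (type %in% c("A3SS", "A5SS")) {
    plus <- event$strand == "+"
    shared <- event$a1
    alts <- c(event$a2, event$a3)
    # a junction interval is (min, max) of donor/acceptor coordinates
    j <- cbind(start = pmin(shared, alts), end = pmax(shared, alts))
    widths <- j[, "end"] - j[, "start"]
    ord <- order(widths)  # shorter intron first = L isoform
    list(L = j[ord[1L], ], S = j[ord[2L], ])
  } else if (type == "ES") {
    list(incl_up = c(start = event$a3, end = event$a1),
         incl_down = c(start = event$a2, end = event$a4),
         excl = c(start = event$a3, end = event$a4))
  } else {
    list(spliced = c(start = event$a1, end = event$a2))
  }
}

#' Which isoform of an event is the long (L, inclusion) isoform
#'
#' @param event One-row event data frame (as produced by the detectors).
#' @return A human-readable description: for IR/ES the retained/included
#'   form, for A3SS/A5SS the alternative site whose junction removes the
#'   shorter intron.
#' @export
assign_long_isoform <- function(event) {
  type <- event$event_type
  if (type == "IR") return("intron_retained")
  if (type == "ES") return("exon_included")
  m <- event_member_junctions(event)
  alt_site <- setdiff(c(m$L[["start"]], m$L[["end"]]), event$a1)
  paste0("junction_", m$L[["start"]], "-", m$L[["end"]],
         "_alt_site_", alt_site)
}

# depth at a single 0-based position
depth_at <- function(coverage, chrom, pos) {
  hit <- coverage$chrom == chrom & coverage$start <= pos &
    coverage$end > pos
  if (any(hit)) sum(coverage$depth[hit]) else 0
}

#' Inclusion and exclusion read counts for events in one individual
#'
#' Looks up the member junction read counts (and, for intron retention,
#' boundary coverage depth) of each event in one individual's evidence.
#' Events with no evidence get counts (0, 0) and an undefined frequency.
#'
#' @param events Event data frame (rows from a catalog).
#' @param junctions Junction data frame for the individual (the same
#'   filtered set used for detection).
#' @param coverage Coverage data frame for the individual (needed for
#'   IR events; may be `NULL` otherwise).
#' @return Data frame `key`, `event_type`, `inclusion`, `exclusion`.
#' @export
count_supporting_reads <- function(events, junctions, coverage = NULL) {
  jc <- stats::setNames(junctions$read_count, junction_key(junctions))
  getc <- function(chrom, strand, start, end) {
    v <- jc[paste(chrom, strand, start, end, sep = "|")]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  n <- nrow(events)
  inclusion <- exclusion <- integer(n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    m <- event_member_junctions(ev)
    if (ev$event_type %in% c("A3SS", "A5SS")) {
      inclusion[i] <- getc(ev$chrom, ev$strand, m$L[["start"]],
                           m$L[["end"]])
      exclusion[i] <- getc(ev$chrom, ev$strand, m$S[["start"]],
                           m$S[["end"]])
    } else if (ev$event_type == "ES") {
      up <- getc(ev$chrom, ev$strand, m$incl_up[["start"]],
                 m$incl_up[["end"]])
      down <- getc(ev$chrom, ev$strand, m$incl_down[["start"]],
                   m$incl_down[["end"]])
      inclusion[i] <- as.integer(floor((up + down) / 2))
      exclusion[i] <- getc(ev$chrom, ev$strand, m$excl[["start"]],
                           m$excl[["end"]])
    } else {  # IR
      if (is.null(coverage)) {
        inclusion[i] <- 0L
      } else {
        d1 <- depth_at(coverage, ev$chrom, ev$a1)        # first intron base
        d2 <- depth_at(coverage, ev$chrom, ev$a2 - 1L)   # last intron base
        inclusion[i] <- as.integer(floor((d1 + d2) / 2))
      }
      exclusion[i] <- getc(ev$chrom, ev$strand, m$spliced[["start"]],
                           m$spliced[["end"]])
    }
  }
  data.frame(key = events$key, event_type = events$event_type,
             inclusion = inclusion, exclusion = exclusion,
             stringsAsFactors = FALSE)
}

#' Isoform(L) frequency
#'
#' `inclusion / (inclusion + exclusion)`; the long-isoform fraction of
#' an event. Undefined (NA) when both counts are zero — undefined
#' frequencies propagate and are never treated as 0.
#'
#' @param inclusion Inclusion (long-isoform) read count(s).
#' @param exclusion Exclusion (short-isoform) read count(s).
#' @return Numeric in \[0, 1\], `NA` where both counts are zero.
#' @examples
#' l_frequency(12, 4)  # 0.75
#' @export
l_frequency <- function(inclusion, exclusion) {
  if (any(inclusion < 0) || any(exclusion < 0)) {
    stop("counts must be non-negative")
  }
  tot <- inclusion + exclusion
  ifelse(tot > 0, inclusion / tot, NA_real_)
}

#' Quantify all events of a catalog in one individual
#'
#' @param catalog An `spl_catalog`.
#' @param junctions Junction data frame for the same individual.
#' @param coverage Coverage data frame for the same individual (or
#'   `NULL`; IR inclusion counts then fall back to 0).
#' @return Data frame `key`, `event_type`, `individual_id`, `inclusion`,
#'   `exclusion`, `l_frequency`.
#' @export
quantify_catalog <- function(catalog, junctions, coverage = NULL) {
  stopifnot(inherits(catalog, "spl_catalog"))
  q <- count_supporting_reads(catalog$events, junctions, coverage)
  data.frame(key = q$key, event_type = q$event_type,
             individual_id = catalog$individual_id,
             inclusion = q$inclusion, exclusion = q$exclusion,
             l_frequency = l_frequency(q$inclusion, q$exclusion),
             stringsAsFactors = FALSE)
}
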