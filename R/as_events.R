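# Detection and classification of alternative-splicing events from
# filtered junction evidence plus per-base coverage.
#
# Four event classes are produced:
#   IR    intron retention: an intron covered at depth >= 1 over its full
#         length in an individual where its spliced junction passed the
#         support filter.
#   A3SS  one donor (5'SS) spliced to two alternative acceptors (3'SS).
#   A5SS  one acceptor spliced to two alternative donors.
#   ES    an exclusion junction spanning a complete internal annotated
#         exon whose two inclusion junctions are also observed.
#
# Alternative-site groups with k alternatives yield all k(k-1)/2
# unordered pairs, one event per pair, so every event has exactly two
# isoforms and the long-isoform frequency is always well defined.
#
# Event identity across individuals is the key string, a pure function
# of (type, chrom, strand, anchor coordinates).

event_columns <- c("event_type", "chrom", "strand",
                   "a1", "a2", "a3", "a4", "key")

empty_events <- function() {
  data.frame(event_type = character(), chrom = character(),
             strand = character(), a1 = integer(), a2 = integer(),
             a3 = integer(), a4 = integer(), key = character(),
             stringsAsFactors = FALSE)
}

make_event_key <- function(type, chrom, strand, a1, a2, a3, a4) {
  ifelse(type == "IR",
         paste0("IR|", chrom, "|", strand, "|", a1, "-", a2),
         ifelse(type == "A3SS",
                paste0("A3SS|", chrom, "|", strand, "|", a1, "|",
                       a2, "/", a3),
                ifelse(type == "A5SS",
                       paste0("A5SS|", chrom, "|", strand, "|",
                              a2, "/", a3, "|", a1),
                       paste0("ES|", chrom, "|", strand, "|", a1, "-", a2,
                              "|", a3, "-", a4))))
}

# donor (5'SS) and acceptor (3'SS) coordinates of a junction, strand-aware
junction_sites <- function(j) {
  plus <- j$strand == "+"
  list(donor = ifelse(plus, j$intron_start, j$intron_end),
       acceptor = ifelse(plus, j$intron_end, j$intron_start))
}

#' Detect alternative 3'/5' splice-site events
#'
#' Junctions are grouped by their shared donor: every unordered pair of
#' distinct acceptors spliced to the same donor is one A3SS event.
#' Symmetrically, junctions grouped by shared acceptor yield one A5SS
#' event per pair of distinct donors. Donor/acceptor roles follow the
#' strand, so the same coordinates on opposite strands classify
#' differently. Unstranded junctions are skipped with a warning.
#'
#' @param junctions Filtered junction data frame for one individual.
#' @return Event data frame. For A3SS the anchors are `a1` = shared
#'   donor, `a2` < `a3` the alternative acceptors; for A5SS `a1` = shared
#'   acceptor, `a2` < `a3` the alternative donors.
#' @export
detect_alt_ss <- function(junctions) {
  j <- junctions[!duplicated(junction_key(junctions)), , drop = FALSE]
  stranded <- j$strand %in% c("+", "-")
  if (any(!stranded)) {
    warning(sum(!stranded), " unstranded junction(s) skipped")
    j <- j[stranded, , drop = FALSE]
  }
  if (!nrow(j)) return(empty_events())
  sites <- junction_sites(j)

  pair_events <- function(shared, alt, type) {
    grp <- paste(j$chrom, j$strand, shared, sep = "|")
    rows <- lapply(split(seq_len(nrow(j)), grp), function(idx) {
      alts <- sort(unique(alt[idx]))
      if (length(alts) < 2L) return(NULL)
      pairs <- utils::combn(alts, 2L)
      data.frame(event_type = type, chrom = j$chrom[idx[1L]],
                 strand = j$strand[idx[1L]], a1 = shared[idx[1L]],
                 a2 = pairs[1L, ], a3 = pairs[2L, ], a4 = NA_integer_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  out <- rbind(pair_events(sites$donor, sites$acceptor, "A3SS"),
               pair_events(sites$acceptor, sites$donor, "A5SS"))
  if (is.null(out)) return(empty_events())
  out$key <- make_event_key(out$event_type, out$chrom, out$strand,
                            out$a1, out$a2, out$a3, out$a4)
  rownames(out) <- NULL
  out[, event_columns]
}

# merged intervals with depth >= min_depth, as a per-chrom IRangesList
covered_ranges <- function(coverage, min_depth = 1) {
  cov <- coverage[coverage$depth >= min_depth, , drop = FALSE]
  lapply(split(cov, cov$chrom), function(d) {
    IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
  })
}

#' Detect intron-retention events
#'
#' Candidate introns are the introns implied by the filtered junctions
#' together with annotated introns; an IR event is called for an intron
#' iff (a) every base of the intron has coverage depth >= 1 in this
#' individual and (b) the spliced junction exactly matching the intron
#' passed the support filter. Because (b) requires the junction,
#' annotated introns lacking a filtered junction can never qualify, so
#' the scan runs over the filtered junction set.
#'
#' @param junctions Filtered junction data frame for one individual.
#' @param coverage Per-base coverage data frame
#'   (`chrom`,`start`,`end`,`depth`) for the same individual.
#' @return Event data frame with `a1`,`a2` the intron interval.
#' @export
detect_ir <- function(junctions, coverage) {
  j <- junctions[!duplicated(junction_key(junctions)), , drop = FALSE]
  if (!nrow(j)) return(empty_events())
  covr <- covered_ranges(coverage, 1)
  full <- vapply(seq_len(nrow(j)), function(i) {
    r <- covr[[j$chrom[i]]]
    if (is.null(r)) return(FALSE)
    intron <- IRanges::IRanges(j$intron_start[i] + 1L, j$intron_end[i])
    length(IRanges::findOverlaps(intron, r, type = "within")) > 0L
  }, logical(1))
  if (!any(full)) return(empty_events())
  out <- data.frame(event_type = "IR", chrom = j$chrom[full],
                    strand = j$strand[full],
                    a1 = j$intron_start[full], a2 = j$intron_end[full],
                    a3 = NA_integer_, a4 = NA_integer_,
                    stringsAsFactors = FALSE)
  out$key <- make_event_key(out$event_type, out$chrom, out$strand,
                            out$a1, out$a2, out$a3, out$a4)
  rownames(out) <- NULL
  out[, event_columns]
}

#' Detect exon-skipping events
#'
#' An ES event is called when a filtered junction (the exclusion
#' junction) strictly contains a complete internal annotated exon and
#' both inclusion junctions are present in the filtered set: the
#' upstream junction `(exclusion_start, exon_start)` and the downstream
#' junction `(exon_end, exclusion_end)`. One event is emitted per
#' (exclusion junction, skipped exon) pair, so a junction spanning two
#' exons yields two events.
#'
#' @param junctions Filtered junction data frame for one individual.
#' @param annotation An `spl_annotation` (source of internal exons).
#' @return Event data frame with `a1`,`a2` the skipped exon interval and
#'   `a3`,`a4` the exclusion junction interval.
#' @export
detect_es <- function(junctions, annotation) {
  stopifnot(inherits(annotation, "spl_annotation"))
  j <- junctions[!duplicated(junction_key(junctions)), , drop = FALSE]
  ex <- annotation$exons[annotation$exons$internal, , drop = FALSE]
  ex <- ex[!duplicated(paste(ex$chrom, ex$strand, ex$start, ex$end)), ,
           drop = FALSE]
  if (!nrow(j) || !nrow(ex)) return(empty_events())
  jkeys <- junction_key(j)
  rows <- vector("list", nrow(j))
  for (i in seq_len(nrow(j))) {
    cand <- ex$chrom == j$chrom[i] & ex$strand == j$strand[i] &
      ex$start > j$intron_start[i] & ex$end < j$intron_end[i]
    if (!any(cand)) next
    e <- ex[cand, , drop = FALSE]
    up <- paste(j$chrom[i], j$strand[i], j$intron_start[i], e$start,
                sep = "|")
    down <- paste(j$chrom[i], j$strand[i], e$end, j$intron_end[i],
                  sep = "|")
    ok <- up %in% jkeys & down %in% jkeys
    if (!any(ok)) next
    rows[[i]] <- data.frame(event_type = "ES", chrom = j$chrom[i],
                            strand = j$strand[i],
                            a1 = e$start[ok], a2 = e$end[ok],
                            a3 = j$intron_start[i], a4 = j$intron_end[i],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty_events())
  out$key <- make_event_key(out$event_type, out$chrom, out$strand,
                            out$a1, out$a2, out$a3, out$a4)
  rownames(out) <- NULL
  out[, event_columns]
}

# assign each event to the gene whose collapsed span contains its anchor
# span (same chrom and strand); ties broken by lexicographic gene_id
assign_genes <- function(events, annotation) {
  if (!nrow(events)) {
    events$gene_id <- character(0)
    return(events)
  }
  lo <- pmin(events$a1, events$a2,
             ifelse(is.na(events$a3), events$a1, events$a3),
             ifelse(is.na(events$a4), events$a1, events$a4))
  hi <- pmax(events$a1, events$a2,
             ifelse(is.na(events$a3), events$a2, events$a3),
             ifelse(is.na(events$a4), events$a2, events$a4))
  g <- annotation$genes[order(annotation$genes$gene_id), , drop = FALSE]
  gene_id <- rep(NA_character_, nrow(events))
  for (i in seq_len(nrow(events))) {
    hit <- which(g$chrom == events$chrom[i] &
                   g$strand == events$strand[i] &
                   g$span_start <= lo[i] & g$span_end >= hi[i])
    if (length(hit)) gene_id[i] <- g$gene_id[hit[1L]]
  }
  events$gene_id <- gene_id
  events
}

#' Build the per-individual event catalog
#'
#' Runs the three detectors, deduplicates by event key, and assigns each
#' event to the gene whose collapsed span contains its anchors (events
#' outside every gene keep `gene_id = NA` and are excluded from the AS
#' gene count). Without coverage the IR detector is skipped with a
#' warning.
#'
#' @param individual_id Individual label stored in the catalog.
#' @param junctions Filtered junction data frame for this individual.
#' @param coverage Per-base coverage data frame, or `NULL`.
#' @param annotation An `spl_annotation`.
#' @return Object of class `spl_catalog`: list with `individual_id`,
#'   `events` (data frame incl. `gene_id`), `type_counts` (named count
#'   per event type) and `n_as_genes`.
#' @export
build_catalog <- function(individual_id, junctions, coverage, annotation) {
  ev <- rbind(detect_alt_ss(junctions),
              if (is.null(coverage)) {
                warning("no coverage for ", individual_id,
                        "; intron-retention detection skipped")
                empty_events()
              } else {
                detect_ir(junctions, coverage)
              },
              detect_es(junctions, annotation))
  ev <- ev[!duplicated(ev$key), , drop = FALSE]
  ev <- ev[order(ev$key), , drop = FALSE]
  rownames(ev) <- NULL
  ev <- assign_genes(ev, annotation)
  types <- c("IR", "A3SS", "A5SS", "ES")
  tc <- vapply(types, function(t) sum(ev$event_type == t), integer(1))
  structure(list(individual_id = individual_id, events = ev,
                 type_counts = tc,
                 n_as_genes = length(unique(stats::na.omit(ev$gene_id)))),
            class = "spl_catalog")
}

#' @export
print.spl_catalog <- function(x, ...) {
  cat("spl_catalog for", x$individual_id, "-", nrow(x$events),
      "events in", x$n_as_genes, "genes\n")
  print(x$type_counts)
  invisible(x)
}

#' Cross-individual event presence and conservation
#'
#' Matches events across individuals by key and tabulates, per event
#' type, how many distinct events occur in exactly 1 individual, in at
#' least `k_high` individuals, and in all individuals.
#'
#' @param catalogs List of `spl_catalog` objects (one per individual).
#' @param k_high Threshold for the "found in >= k" row.
#' @return List with `presence` (0/1 matrix, events x individuals),
#'   `types` (named type per event key) and `summary` (the conservation
#'   summary data frame from [conservation_summary()], with raw
#'   percentage columns).
#' @export
presence_and_conservation <- function(catalogs, k_high = 15L) {
  if (!length(catalogs)) stop("need at least one catalog")
  inds <- vapply(catalogs, function(cc) cc$individual_id, character(1))
  evs <- do.call(rbind, lapply(catalogs, function(cc) {
    if (!nrow(cc$events)) return(NULL)
    data.frame(key = cc$events$key, type = cc$events$event_type,
               individual = cc$individual_id, stringsAsFactors = FALSE)
  }))
  if (is.null(evs)) {
    return(list(presence = matrix(0L, 0, length(inds),
                                  dimnames = list(NULL, inds)),
                types = character(0),
                summary = conservation_summary(data.frame(
                  event_type = c("A3SS", "A5SS", "IR", "ES"),
                  n_events = 0L, n_in_1 = 0L, n_in_ge_k = 0L,
                  n_in_all = 0L), k_high, length(inds))))
  }
  keys <- sort(unique(evs$key))
  pres <- matrix(0L, length(keys), length(inds),
                 dimnames = list(keys, inds))
  pres[cbind(match(evs$key, keys), match(evs$individual, inds))] <- 1L
  types <- stats::setNames(evs$type[match(keys, evs$key)], keys)
  nshared <- rowSums(pres)
  per_type <- function(t) {
    sel <- types == t
    c(n_events = sum(sel), n_in_1 = sum(sel & nshared == 1L),
      n_in_ge_k = sum(sel & nshared >= k_high),
      n_in_all = sum(sel & nshared == length(inds)))
  }
  tt <- c("A3SS", "A5SS", "IR", "ES")
  counts <- as.data.frame(t(vapply(tt, per_type, numeric(4))))
  counts <- cbind(event_type = tt, counts, stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(presence = pres, types = types,
       summary = conservation_summary(counts, k_high, length(inds)))
}

#' Conservation summary arithmetic
#'
#' Given per-type event totals and conservation counts, appends a Total
#' row and the percentage columns: each type's share of all events, and
#' within each type the percentage of events in exactly 1, in >= k, and
#' in all individuals. Percentages are returned unrounded; report
#' formatting decides the printed precision.
#'
#' @param counts Data frame with columns `event_type`, `n_events`,
#'   `n_in_1`, `n_in_ge_k`, `n_in_all` (one row per type).
#' @param k_high The k used for the `n_in_ge_k` column (recorded as an
#'   attribute).
#' @param n_individuals Number of individuals (recorded as an attribute).
#' @return The input with a `Total` row and percentage columns
#'   `pct_of_events`, `pct_in_1`, `pct_in_ge_k`, `pct_in_all`.
#' @export
conservation_summary <- function(counts, k_high = 15L,
                                 n_individuals = NA_integer_) {
  need <- c("event_type", "n_events", "n_in_1", "n_in_ge_k", "n_in_all")
  stopifnot(all(need %in% names(counts)))
  total <- data.frame(event_type = "Total",
                      n_events = sum(counts$n_events),
                      n_in_1 = sum(counts$n_in_1),
                      n_in_ge_k = sum(counts$n_in_ge_k),
                      n_in_all = sum(counts$n_in_all),
                      stringsAsFactors = FALSE)
  out <- rbind(counts[, need], total)
  grand <- total$n_events
  out$pct_of_events <- if (grand > 0) out$n_events / grand * 100 else NA_real_
  pct <- function(num) ifelse(out$n_events > 0,
                              num / out$n_events * 100, NA_real_)
  out$pct_in_1 <- pct(out$n_in_1)
  out$pct_in_ge_k <- pct(out$n_in_ge_k)
  out$pct_in_all <- pct(out$n_in_all)
  attr(out, "k_high") <- k_high
  attr(out, "n_individuals") <- n_individuals
  out
}
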