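# Fixture builders shared across test files. Everything is generated in
# code; no stored data files.

# one junction evidence row
jrow <- function(chrom, start, end, strand, count = 10L,
                 distinct = NULL, overhang = 20L, id = "A") {
  data.frame(chrom = chrom, strand = strand,
             intron_start = as.integer(start),
             intron_end = as.integer(end),
             read_count = as.integer(count),
             distinct_positions = as.integer(
               if (is.null(distinct)) count else distinct),
             min_overhang = as.integer(overhang),
             individual_id = id, stringsAsFactors = FALSE)
}

jtab <- function(...) do.call(rbind, list(...))

# write a GFF3 for a list of genes; each gene is
# list(id, chrom, strand, transcripts = list of exon matrices
# (1-based closed start/end rows))
write_gff3_fixture <- function(genes, path = tempfile(fileext = ".gff3")) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lo <- min(vapply(g$transcripts, function(t) min(t[, 1L]), numeric(1)))
    hi <- max(vapply(g$transcripts, function(t) max(t[, 2L]), numeric(1)))
    lines <- c(lines, sprintf("%s\tt\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$chrom, lo, hi, g$strand, g$id))
    for (ti in seq_along(g$transcripts)) {
      tid <- paste0(g$id, ".", ti)
      tx <- g$transcripts[[ti]]
      lines <- c(lines,
                 sprintf("%s\tt\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$chrom, min(tx[, 1L]), max(tx[, 2L]), g$strand,
                         tid, g$id),
                 sprintf("%s\tt\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$chrom, tx[, 1L], tx[, 2L], g$strand, tid))
    }
  }
  writeLines(lines, path)
  path
}

# 3-exon gene on '+' used by several tests: exons (1-based closed)
# 1-100, 201-300, 401-500 -> internal coords 0-100, 200-300, 400-500,
# introns [100,200) and [300,400)
simple_gene_ann <- function(chrom = "chr1", strand = "+") {
  suppressMessages(load_annotation(write_gff3_fixture(list(
    list(id = "g1", chrom = chrom, strand = strand,
         transcripts = list(cbind(c(1, 201, 401), c(100, 300, 500))))
  ))))
}

cov_df <- function(chrom, start, end, depth) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), depth = depth,
             stringsAsFactors = FALSE)
}
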