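# AS event detection: alternative splice sites, intron retention,
# exon skipping, catalogs and conservation.

test_that("one donor spliced to two acceptors yields one A3SS on '+'", {
  j <- jtab(jrow("chr1", 100, 200, "+"), jrow("chr1", 100, 230, "+"))
  ev <- detect_alt_ss(j)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "A3SS")
  expect_equal(ev$a1, 100L)
  expect_equal(c(ev$a2, ev$a3), c(200L, 230L))
})

test_that("the same coordinates on '-' swap to an A5SS", {
  j <- jtab(jrow("chr1", 100, 200, "-"), jrow("chr1", 100, 230, "-"))
  ev <- detect_alt_ss(j)
  expect_equal(ev$event_type, "A5SS")
  # orientation-explicit oracle agrees
  expect_equal(sort(ev$key), brute_alt_ss_keys(j))
})

test_that("k alternative sites produce k(k-1)/2 pairwise events", {
  ends <- c(200L, 230L, 260L)
  j <- do.call(rbind, lapply(ends, function(e) jrow("chr1", 100, e, "+")))
  ev <- detect_alt_ss(j)
  expect_equal(nrow(ev), 3L)
  expect_equal(sort(ev$key), brute_alt_ss_keys(j))
  for (k in 2:5) {
    jk <- do.call(rbind, lapply(seq_len(k), function(i)
      jrow("chr2", 1000, 1100 + i * 30, "+")))
    expect_equal(nrow(detect_alt_ss(jk)), k * (k - 1) / 2)
  }
})

test_that("unstranded junctions are skipped with a warning", {
  j <- jtab(jrow("chr1", 100, 200, "."), jrow("chr1", 100, 230, "+"))
  expect_warning(ev <- detect_alt_ss(j), "unstranded")
  expect_equal(nrow(ev), 0L)
})

test_that("intron retention needs full coverage and a passing junction", {
  j <- jrow("chr1", 100, 200, "+")
  full <- cov_df("chr1", 90, 210, 3)
  expect_equal(nrow(detect_ir(j, full)), 1L)
  # one internal base at depth 0 kills the call
  gap <- rbind(cov_df("chr1", 90, 150, 3), cov_df("chr1", 151, 210, 3))
  expect_equal(nrow(detect_ir(j, gap)), 0L)
  # junction absent from the filtered set: no candidate at all
  expect_equal(nrow(detect_ir(j[0, ], full)), 0L)
  # full coverage assembled from abutting intervals still counts
  pieces <- rbind(cov_df("chr1", 100, 150, 1), cov_df("chr1", 150, 200, 2))
  expect_equal(nrow(detect_ir(j, pieces)), 1L)
})

test_that("a junction that fails the support filter cannot give IR", {
  j <- jrow("chr1", 100, 200, "+", count = 1L)
  kept <- suppressMessages(filter_junctions(j, filter_config()))
  full <- cov_df("chr1", 90, 210, 3)
  expect_equal(nrow(detect_ir(kept, full)), 0L)
})

test_that("exon skipping requires the full junction triple", {
  ann <- simple_gene_ann()  # exons [0,100) [200,300) [400,500)
  incl_up <- jrow("chr1", 100, 200, "+")
  incl_down <- jrow("chr1", 300, 400, "+")
  excl <- jrow("chr1", 100, 400, "+")
  ev <- detect_es(jtab(incl_up, incl_down, excl), ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "ES")
  expect_equal(c(ev$a1, ev$a2), c(200L, 300L))   # skipped exon
  expect_equal(c(ev$a3, ev$a4), c(100L, 400L))   # exclusion junction
  # drop one inclusion junction: no event
  expect_equal(nrow(detect_es(jtab(incl_up, excl), ann)), 0L)
  # oracle agreement
  j3 <- jtab(incl_up, incl_down, excl)
  expect_equal(sort(ev$key), brute_es_keys(j3, ann))
})

test_that("an exclusion junction spanning two exons yields two events", {
  # 4-exon gene: exons 1-100, 201-300, 401-500, 601-700 (1-based)
  ann <- suppressMessages(load_annotation(write_gff3_fixture(list(
    list(id = "g4", chrom = "chr1", strand = "+",
         transcripts = list(cbind(c(1, 201, 401, 601),
                                  c(100, 300, 500, 700))))))))
  j <- jtab(jrow("chr1", 100, 200, "+"),   # E1 -> E2
            jrow("chr1", 300, 400, "+"),   # E2 -> E3
            jrow("chr1", 500, 600, "+"),   # E3 -> E4
            jrow("chr1", 100, 600, "+"),   # E1 -> E4 skips E2 and E3...
            jrow("chr1", 100, 400, "+"),   # E1 -> E3 skips E2
            jrow("chr1", 300, 600, "+"))   # E2 -> E4 skips E3
  ev <- detect_es(j, ann)
  expect_equal(sort(ev$key), brute_es_keys(j, ann))
  # the E1->E4 junction alone: inclusion junctions for E2 (E1->E2 and
  # E2->E4) and for E3 (E1->E3 and E3->E4) are all present: two events
  e14 <- ev[ev$a3 == 100 & ev$a4 == 600, ]
  expect_equal(nrow(e14), 2L)
})

test_that("detection equals the brute-force scan on random sets", {
  ann <- suppressMessages(load_annotation(write_gff3_fixture(list(
    list(id = "g1", chrom = "chr1", strand = "+",
         transcripts = list(cbind(c(1, 201, 401, 601, 801),
                                  c(100, 300, 500, 700, 900)))),
    list(id = "g2", chrom = "chr1", strand = "-",
         transcripts = list(cbind(c(2001, 2201, 2401),
                                  c(2100, 2300, 2500))))))))
  for (seed in 1:5) {
    j <- random_junctions(40, seed)
    expect_equal(sort(detect_alt_ss(j)$key), brute_alt_ss_keys(j))
    expect_equal(sort(detect_es(j, ann)$key), brute_es_keys(j, ann))
  }
})

test_that("IR detection equals the per-base oracle on random coverage", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 12
    starts <- sample(seq(100, 3000, by = 120), n)
    j <- do.call(rbind, lapply(starts, function(s)
      jrow("chr1", s, s + sample(40:100, 1), "+")))
    cov <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) return(NULL)
      lo <- j$intron_start[i] + sample(c(0L, 3L), 1)  # sometimes late start
      cov_df("chr1", lo, j$intron_end[i] + sample(c(0L, -2L), 1),
             sample(1:4, 1))
    }))
    if (is.null(cov)) cov <- cov_df("chr1", 0, 1, 1)
    expect_equal(sort(detect_ir(j, cov)$key), brute_ir_keys(j, cov))
  }
})

test_that("detection is deterministic and monotone in evidence", {
  j <- random_junctions(30, 99)
  k1 <- sort(detect_alt_ss(j)$key)
  k2 <- sort(detect_alt_ss(j[sample(nrow(j)), ])$key)
  expect_identical(k1, k2)  # order-insensitive, stable keys
  extra <- jrow("chr1", 100, 5000, "+")
  k3 <- sort(detect_alt_ss(rbind(j, extra))$key)
  expect_true(all(k1 %in% k3))
})

test_that("catalogs deduplicate keys, assign genes, count AS genes", {
  ann <- simple_gene_ann()
  j <- jtab(jrow("chr1", 100, 200, "+"),    # intron 1 (IR via coverage)
            jrow("chr1", 100, 230, "+"),    # alt acceptor -> A3SS
            jrow("chr1", 300, 400, "+"),
            jrow("chr1", 100, 400, "+"))    # exclusion junction -> ES
  cov <- cov_df("chr1", 95, 205, 2)
  cat1 <- build_catalog("I1", j, cov, ann)
  expect_s3_class(cat1, "spl_catalog")
  expect_equal(sum(cat1$type_counts), nrow(cat1$events))
  expect_false(any(duplicated(cat1$events$key)))
  expect_gte(cat1$type_counts[["IR"]], 1L)
  expect_gte(cat1$type_counts[["A3SS"]], 1L)
  expect_gte(cat1$type_counts[["ES"]], 1L)
  expect_true(all(na.omit(cat1$events$gene_id) == "g1"))
  expect_equal(cat1$n_as_genes, 1L)
  # empty inputs give an empty catalog
  cat0 <- build_catalog("I2", j[0, ], cov[0, ], ann)
  expect_equal(nrow(cat0$events), 0L)
  expect_equal(cat0$n_as_genes, 0L)
})

test_that("events outside every gene stay unassigned", {
  ann <- simple_gene_ann()
  j <- jtab(jrow("chr9", 100, 200, "+"), jrow("chr9", 100, 230, "+"))
  cat1 <- suppressWarnings(build_catalog("I1", j, NULL, ann))
  expect_true(all(is.na(cat1$events$gene_id)))
  expect_equal(cat1$n_as_genes, 0L)
})

test_that("missing coverage skips IR with a warning", {
  ann <- simple_gene_ann()
  j <- jrow("chr1", 100, 200, "+")
  expect_warning(cat1 <- build_catalog("I1", j, NULL, ann),
                 "retention")
  expect_equal(cat1$type_counts[["IR"]], 0L)
})

test_that("single-individual conservation puts everything in bin 1", {
  ann <- simple_gene_ann()
  j <- jtab(jrow("chr1", 100, 200, "+"), jrow("chr1", 100, 230, "+"))
  cat1 <- suppressWarnings(build_catalog("I1", j, NULL, ann))
  pc <- presence_and_conservation(list(cat1), k_high = 1L)
  s <- pc$summary
  expect_equal(s$n_in_1[s$event_type == "Total"],
               s$n_events[s$event_type == "Total"])
})

test_that("conservation tallies match brute force on random catalogs", {
  ann <- simple_gene_ann()
  set.seed(5)
  cats <- lapply(1:4, function(i) {
    j <- random_junctions(25, 100 + i)
    suppressWarnings(build_catalog(paste0("I", i), j, NULL, ann))
  })
  pc <- presence_and_conservation(cats, k_high = 3L)
  # brute force from the raw event lists
  allkeys <- unique(unlist(lapply(cats, function(cc) cc$events$key)))
  pres <- sapply(cats, function(cc) allkeys %in% cc$events$key)
  shared <- rowSums(pres)
  s <- pc$summary
  tot <- s[s$event_type == "Total", ]
  expect_equal(tot$n_events, length(allkeys))
  expect_equal(tot$n_in_1, sum(shared == 1))
  expect_equal(tot$n_in_ge_k, sum(shared >= 3))
  expect_equal(tot$n_in_all, sum(shared == 4))
  expect_equal(unname(rowSums(pc$presence)),
               shared[match(rownames(pc$presence), allkeys)])
})
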