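# Synthetic-data generator: determinism, feasibility constraints,
# ground-truth consistency, end-to-end recovery.

test_that("genome generation is byte-deterministic under the seed", {
  cfg <- simulation_config(seed = 1, n_genes = 10)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  t1 <- generate_genome(cfg, f1)
  t2 <- generate_genome(cfg, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(t1$events$key, t2$events$key)
})

test_that("configuration constraints are enforced", {
  expect_error(simulation_config(as_mixture = c(IR = .5, A3SS = .3,
                                                A5SS = .1, ES = .2)),
               "sum to 1")
  expect_error(simulation_config(exon_range = c(2L, 2L)),
               "at least 3 exons")
  # pure-IR mixture is feasible with 2-exon genes
  cfg <- simulation_config(seed = 2, n_genes = 15,
                           as_mixture = c(IR = 1, A3SS = 0, A5SS = 0,
                                          ES = 0),
                           exon_range = c(2L, 4L))
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  expect_true(all(tr$events$event_type == "IR"))
})

test_that("ES host genes always have an internal exon", {
  cfg <- simulation_config(seed = 3, n_genes = 60,
                           as_mixture = c(IR = 0, A3SS = 0, A5SS = 0,
                                          ES = 1),
                           exon_range = c(3L, 5L), event_prob = 1)
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  hosts <- tr$genes$n_exons[match(tr$events$gene_id, tr$genes$gene_id)]
  expect_true(all(hosts >= 3L))
})

test_that("truth keys match detection keys on the emitted files", {
  cfg <- simulation_config(seed = 4, n_genes = 30,
                           below_support_fraction = 0)
  d <- tempfile(); dir.create(d)
  sim <- simulate_study(cfg, d)
  ann <- suppressMessages(load_annotation(sim$annotation))
  id <- cfg$individuals[1]
  j <- suppressMessages(filter_junctions(
    read_junctions(sim$junctions[[id]], "tsv", id)))
  cov <- read_bedgraph(sim$coverage[[id]])
  cat1 <- build_catalog(id, j, cov, ann)
  # every truth event whose evidence passed filters is in the catalog
  # with the right type; fail-support events were disabled above
  draws <- simulate_individual(sim$truth, cfg, id, tempdir())$draws
  jk <- paste(j$chrom, j$strand, j$intron_start, j$intron_end, sep = "|")
  for (i in seq_len(nrow(sim$truth$events))) {
    ev <- sim$truth$events[i, ]
    n <- draws$n[i]; incl <- draws$inclusion[i]
    expected <- switch(ev$event_type,
      IR = (n - incl) >= 2 && incl >= 1,
      A3SS = incl >= 2 && (n - incl) >= 2,
      A5SS = incl >= 2 && (n - incl) >= 2,
      ES = incl >= 2 && (n - incl) >= 2)
    if (expected) {
      expect_true(ev$key %in% cat1$events$key, label = ev$key)
      got <- cat1$events$event_type[cat1$events$key == ev$key]
      expect_equal(got, ev$event_type)
    }
  }
})

test_that("events designed to fail support never reach catalogs", {
  cfg <- simulation_config(seed = 6, n_genes = 40,
                           below_support_fraction = 1, event_prob = 1)
  d <- tempfile(); dir.create(d)
  sim <- simulate_study(cfg, d)
  ann <- suppressMessages(load_annotation(sim$annotation))
  for (id in cfg$individuals[1:3]) {
    j <- suppressMessages(filter_junctions(
      read_junctions(sim$junctions[[id]], "tsv", id)))
    cov <- read_bedgraph(sim$coverage[[id]])
    cat1 <- build_catalog(id, j, cov, ann)
    expect_false(any(sim$truth$events$key %in% cat1$events$key))
  }
})

test_that("decoy gap introns are never called as retention", {
  cfg <- simulation_config(seed = 7, n_genes = 40,
                           gap_intron_fraction = 1, event_prob = 0.3)
  d <- tempfile(); dir.create(d)
  sim <- simulate_study(cfg, d)
  ann <- suppressMessages(load_annotation(sim$annotation))
  id <- cfg$individuals[1]
  j <- suppressMessages(filter_junctions(
    read_junctions(sim$junctions[[id]], "tsv", id)))
  cov <- read_bedgraph(sim$coverage[[id]])
  ir <- detect_ir(j, cov)
  gap_keys <- sprintf("IR|%s|%s|%d-%d", sim$truth$gap_introns$chrom,
                      sim$truth$gap_introns$strand,
                      sim$truth$gap_introns$start,
                      sim$truth$gap_introns$end)
  expect_false(any(gap_keys %in% ir$key))
})

test_that("simulated L-frequencies are centred on the true p", {
  cfg <- simulation_config(seed = 8, n_genes = 1100, event_prob = 1,
                           shift_fraction = 0,
                           below_support_fraction = 0,
                           individuals = c("A", "B"))
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  # pin the base frequency of every event to 0.75
  tr$events$p_base <- rep(0.75, nrow(tr$events))
  res <- simulate_individual(tr, cfg, "A", tempdir())
  ok <- res$draws$n > 0
  est <- res$draws$inclusion[ok] / res$draws$n[ok]
  expect_gte(length(est), 1000)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.75), 3 * se)
})

test_that("realized type proportions approach the configured mixture", {
  cfg <- simulation_config(seed = 9, n_genes = 600, event_prob = 1)
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  prop <- prop.table(table(factor(tr$events$event_type,
                                  c("IR", "A3SS", "A5SS", "ES"))))
  expect_equal(as.numeric(prop), as.numeric(cfg$as_mixture),
               tolerance = 0.12)
})

test_that("truth JSON round-trips", {
  cfg <- simulation_config(seed = 10, n_genes = 12)
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_equal(back$events$key, tr$events$key)
  expect_equal(back$events$p_base, tr$events$p_base)
  expect_equal(back$genes$true_fpkm, tr$genes$true_fpkm)
  expect_equal(back$groups, tr$groups)
  expect_error(read_truth(tempfile()), "not found")
  # version check
  j <- jsonlite::read_json(f)
  j$version <- 99
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(j, f2, auto_unbox = TRUE)
  expect_error(read_truth(f2), "version")
})

test_that("an eventless truth writes and reads as valid empty", {
  cfg <- simulation_config(seed = 11, n_genes = 5, event_prob = 0)
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  expect_equal(nrow(tr$events), 0L)
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  expect_equal(length(read_truth(f)$events), 0L)
})

test_that("degenerate binomial: p forced to 1 gives all inclusion", {
  cfg <- simulation_config(seed = 12, n_genes = 30, event_prob = 1,
                           shift_fraction = 0,
                           below_support_fraction = 0,
                           individuals = c("A", "B"))
  tr <- generate_genome(cfg, tempfile(fileext = ".gff3"))
  tr$events$p_base <- rep(1, nrow(tr$events))
  res <- simulate_individual(tr, cfg, "A", tempdir())
  expect_equal(res$draws$inclusion, res$draws$n)
})
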