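# Population variation: expression filter, Spearman matrix, clustering,
# Fisher exact tests, BH adjustment, variable-event fractions.

test_that("expression filter keeps only genes at FPKM >= 5 everywhere", {
  events <- data.frame(key = c("e1", "e2", "e3"),
                       gene_id = c("gA", "gB", NA),
                       stringsAsFactors = FALSE)
  expr <- expand.grid(gene_id = c("gA", "gB"),
                      individual_id = c("I1", "I2"),
                      stringsAsFactors = FALSE)
  expr$fpkm <- c(5, 8, 5, 4.9)  # gB dips below 5 in I2
  cfg <- population_config(c("I1", "I2"))
  out <- filter_expressed_events(events, expr, cfg)
  expect_equal(out$key, "e1")
  expect_equal(nrow(filter_expressed_events(events[0, ], expr, cfg)), 0L)
})

test_that("Spearman matrix matches the tie-corrected rank formula", {
  m <- cbind(I1 = c(0.1, 0.4, 0.4, 0.7, 0.9, 0.2),
             I2 = c(0.2, 0.3, 0.5, 0.6, 0.8, 0.2))
  rho <- spearman_matrix(m)
  expect_equal(rho[1, 2], oracle_spearman(m[, 1], m[, 2]))
  expect_equal(rho, t(rho))
  expect_equal(diag(rho), c(I1 = 1, I2 = 1))
  # identical and reversed vectors
  m2 <- cbind(A = 1:6 / 10, B = 1:6 / 10, C = 6:1 / 10)
  rho2 <- spearman_matrix(m2)
  expect_equal(rho2["A", "B"], 1)
  expect_equal(rho2["A", "C"], -1)
})

test_that("Spearman is invariant under monotone transforms", {
  set.seed(3)
  m <- cbind(I1 = runif(20), I2 = runif(20))
  r1 <- spearman_matrix(m)[1, 2]
  m2 <- cbind(I1 = exp(3 * m[, 1]), I2 = m[, 2]^3 + 5)
  expect_equal(spearman_matrix(m2)[1, 2], r1)
})

test_that("pairwise-complete handling and the <2-shared-events flag", {
  m <- cbind(I1 = c(0.1, 0.5, NA, 0.8), I2 = c(0.2, NA, 0.3, 0.9),
             I3 = c(NA, NA, NA, 0.5))
  w <- capture_warnings(rho <- spearman_matrix(m))
  expect_true(length(w) >= 1 && all(grepl("fewer than 2", w)))
  expect_true(is.na(rho["I1", "I3"]))
  ok <- complete.cases(m[, 1:2])
  expect_equal(rho["I1", "I2"], oracle_spearman(m[ok, 1], m[ok, 2]))
})

test_that("average-linkage clustering merges tight groups first", {
  # two groups with high within-, low between-correlation
  rho <- rbind(c(1, .9, .3, .3), c(.9, 1, .3, .3),
               c(.3, .3, 1, .85), c(.3, .3, .85, 1))
  dimnames(rho) <- list(c("a1", "a2", "b1", "b2"),
                        c("a1", "a2", "b1", "b2"))
  hc <- cluster_individuals(rho)
  groups <- cutree(hc, 2)
  expect_equal(groups[["a1"]], groups[["a2"]])
  expect_equal(groups[["b1"]], groups[["b2"]])
  expect_false(groups[["a1"]] == groups[["b1"]])
  expect_true(all(diff(hc$height) >= -1e-12))
  # exhaustive 4-leaf average-linkage oracle: first merge is the
  # closest pair, final height is the mean between-block distance
  d <- 1 - rho
  expect_equal(min(hc$height), min(d[upper.tri(d)]))
  expect_equal(max(hc$height), mean(c(d["a1", "b1"], d["a1", "b2"],
                                      d["a2", "b1"], d["a2", "b2"])))
  # degenerate inputs
  expect_error(cluster_individuals(matrix(c(1, NA, NA, 1), 2)), "undefined")
  # three leaves, distances (0.1, 0.5, 0.5): closest pair at height 0.1
  rho3 <- rbind(c(1, .9, .5), c(.9, 1, .5), c(.5, .5, 1))
  dimnames(rho3) <- list(letters[1:3], letters[1:3])
  expect_equal(min(cluster_individuals(rho3)$height), 0.1)
})

test_that("equal correlations give equal merge heights", {
  rho <- matrix(0.4, 4, 4); diag(rho) <- 1
  dimnames(rho) <- list(letters[1:4], letters[1:4])
  hc <- cluster_individuals(rho)
  expect_equal(hc$height, rep(0.6, 3))
})

test_that("Newick export round-trips through ape", {
  rho <- rbind(c(1, .9, .3), c(.9, 1, .3), c(.3, .3, 1))
  dimnames(rho) <- list(c("x", "y", "z"), c("x", "y", "z"))
  f <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cluster_individuals(rho), f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("x", "y", "z"))
})

test_that("Fisher p-values match hand cases and stats::fisher.test", {
  expect_equal(fisher_event_pair(10, 10, 10, 10), 1)
  expect_equal(fisher_event_pair(0, 0, 5, 5), 1)    # degenerate row
  expect_equal(fisher_event_pair(5, 0, 7, 0), 1)    # degenerate column
  expect_equal(fisher_event_pair(12, 4, 4, 12),
               oracle_fisher(12, 4, 4, 12))
  # independent library cross-check on random tables
  set.seed(8)
  for (i in 1:50) {
    t4 <- as.integer(rpois(4, 7))
    p_pkg <- fisher_event_pair(t4[1], t4[2], t4[3], t4[4])
    p_ref <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  adj <- bh_adjust(p, 0.05)
  expect_equal(adj$adjusted, rep(0.04, 4))
  expect_true(all(adj$significant))
  expect_true(all(adj$adjusted >= p))
  expect_false(any(bh_adjust(rep(1, 5))$significant))
  expect_true(bh_adjust(0.04, 0.05)$significant)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # random vectors against the direct max-k definition
  set.seed(13)
  for (i in 1:10) {
    pv <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(pv)$adjusted, oracle_bh(pv))
  }
})

test_that("BH flags are monotone in q", {
  set.seed(19)
  pv <- runif(100, 0, 0.2)
  f1 <- bh_adjust(pv, 0.01)$significant
  f2 <- bh_adjust(pv, 0.05)$significant
  f3 <- bh_adjust(pv, 0.20)$significant
  expect_true(all(f1 <= f2) && all(f2 <= f3))
})

test_that("group testing flags shifted events and reports fractions", {
  set.seed(31)
  n_ev <- 60; depth <- 80
  keys <- sprintf("ev%02d", seq_len(n_ev))
  p0 <- runif(n_ev, 0.3, 0.7)
  inds <- c("I1", "I2", "I3")
  quants <- do.call(rbind, lapply(inds, function(id) {
    p <- p0
    if (id == "I3") p[1:10] <- pmin(p[1:10] + 0.4, 0.98)  # 10 shifted
    x <- rbinom(n_ev, depth, p)
    data.frame(key = keys, event_type = "A3SS", individual_id = id,
               inclusion = x, exclusion = depth - x,
               l_frequency = x / depth, stringsAsFactors = FALSE)
  }))
  cfg <- population_config(inds, fdr_q = 0.05)
  v <- test_splicing_variation(quants, cfg)
  res <- v[["all"]]
  expect_equal(res$n_events_tested, n_ev)
  expect_equal(res$n_events_detected, n_ev)
  flagged_shifted <- mean(keys[1:10] %in% res$variable_keys)
  expect_gte(flagged_shifted, 0.7)
  expect_lte(mean(keys[11:60] %in% res$variable_keys), 0.1)
  expect_equal(variable_event_fraction(v, "all", "tested"),
               length(res$variable_keys) / n_ev)
  expect_error(variable_event_fraction(v, "nope"), "unknown group")
})

test_that("undefined frequencies are excluded, not imputed", {
  quants <- data.frame(
    key = c("e1", "e1", "e2", "e2"), event_type = "A3SS",
    individual_id = c("I1", "I2", "I1", "I2"),
    inclusion = c(10L, 0L, 8L, 12L), exclusion = c(10L, 0L, 12L, 8L),
    l_frequency = c(0.5, NA, 0.4, 0.6), stringsAsFactors = FALSE)
  v <- test_splicing_variation(quants, population_config(c("I1", "I2")))
  expect_equal(unique(v[["all"]]$tests$key), "e2")
  expect_equal(v[["all"]]$n_events_tested, 1L)
  expect_equal(v[["all"]]$n_events_detected, 2L)
})

test_that("excluded individuals do not enter group tests", {
  quants <- do.call(rbind, lapply(c("I1", "I2", "I3"), function(id)
    data.frame(key = "e1", event_type = "IR", individual_id = id,
               inclusion = 10L, exclusion = 10L, l_frequency = 0.5,
               stringsAsFactors = FALSE)))
  cfg <- population_config(c("I1", "I2", "I3"), exclude = "I3")
  v <- test_splicing_variation(quants, cfg)
  expect_false(any(grepl("I3", v[["all"]]$tests$ind_a)) ||
                 any(grepl("I3", v[["all"]]$tests$ind_b)))
})
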