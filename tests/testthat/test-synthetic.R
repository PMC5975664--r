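test_that("benchmark datasets are reproducible and match their design", {
  cfg <- synthetic_config(seed = 5)
  ds1 <- make_benchmark(cfg)
  ds2 <- make_benchmark(cfg)
  expect_identical(ds1$expr, ds2$expr)
  expect_identical(ds1$global$label, ds2$global$label)
  # default design: 150 cells, 10 + 20 branching + 10 non-branching genes
  expect_equal(dim(ds1$expr), c(40, 150))
  expect_equal(sum(ds1$true_branch_time == 0.2, na.rm = TRUE), 10)
  expect_equal(sum(ds1$true_branch_time == 0.8, na.rm = TRUE), 20)
  expect_equal(sum(is.na(ds1$true_branch_time)), 10)
  expect_equal(ds1$global$branch_time, 0.2)
  expect_true(all(ds1$pseudotime >= 0 & ds1$pseudotime <= 1))
  expect_true(!is.unsorted(ds1$pseudotime))
  # trunk labels only before the global branching time
  expect_true(all(ds1$pseudotime[ds1$global$label == "trunk"] < 0.2))
  # the early-bias demonstration design is expressible too
  ds3 <- make_benchmark(synthetic_config(
    gene_groups = data.frame(branch_time = c(0.1, 0.7, NA),
                             n_genes = c(3L, 27L, 10L)),
    noise_variance = 0.001, seed = 1))
  expect_equal(nrow(ds3$expr), 40)
  expect_equal(ds3$global$branch_time, 0.1)
})

test_that("branching draws respect the intersection and rejection rules", {
  set.seed(17)
  times <- seq(0.02, 0.98, length.out = 40)
  for (i in 1:20) {
    g <- sample_branching_gene(times, 0.45, noise_variance = 1e-12)
    post <- which(times >= 0.45)
    d <- g$latent[post, 2] - g$latent[post, 3]
    # accepted draws never cross after the branching point
    expect_false(any(d[-length(d)] * d[-1] < 0))
    # pre-branch cells read the trunk function (zero-noise construction)
    pre <- which(times < 0.45)
    expect_equal(g$y[pre], g$latent[pre, 1], tolerance = 1e-4)
    expect_true(all(g$cell_branch[pre] == "trunk"))
  }
})

test_that("generated expression has the configured marginal moments", {
  set.seed(19)
  times <- c(0.15, 0.5, 0.85)
  n_rep <- 3000
  vals <- t(vapply(seq_len(n_rep), function(i) {
    sample_branching_gene(times, 0.4, noise_variance = 0.5)$y
  }, numeric(3)))
  # marginal variance at each cell = signal variance + noise variance
  expect_equal(unname(apply(vals, 2, var)), rep(2.5, 3), tolerance = 0.15)
  expect_equal(unname(colMeans(vals)), rep(0, 3), tolerance = 0.1)
  nb <- t(vapply(seq_len(n_rep), function(i) {
    sample_nonbranching_gene(times, noise_variance = 0.5)
  }, numeric(3)))
  expect_equal(unname(apply(nb, 2, var)), rep(2.5, 3), tolerance = 0.15)
  # non-branching draws carry no group structure: cells split by an
  # arbitrary coin have indistinguishable means
  set.seed(23)
  pvals <- vapply(1:100, function(i) {
    y <- sample_nonbranching_gene(runif(20), noise_variance = 1)
    t.test(y[1:10], y[11:20])$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("label corruption flips the expected number of post-branch labels", {
  ds <- make_benchmark(synthetic_config(seed = 29))
  g0 <- corrupt_global_labels(ds$global, 0, seed = 1)
  expect_identical(as.character(g0$label), as.character(ds$global$label))
  g3 <- corrupt_global_labels(ds$global, 0.3, seed = 1)
  post <- which(ds$global$label != "trunk")
  flipped <- sum(g3$label[post] != ds$global$label[post])
  n_post <- length(post)
  expect_lt(abs(flipped - 0.3 * n_post), 4 * sqrt(n_post * 0.3 * 0.7))
  expect_true(all(g3$label[-post] == "trunk"))
  expect_error(corrupt_global_labels(ds$global, 0.7), "flip_rate")
})

test_that("balanced subsampling equalises strata and keeps small ones whole", {
  set.seed(31)
  sizes <- c(trunk = 915, "1" = 1662, "2" = 114)
  lab <- rep(names(sizes), sizes)
  n <- length(lab)
  times <- sort(runif(n))
  lab <- lab[order(c(which(lab == "trunk"), which(lab == "1"),
                     which(lab == "2")))]  # keep counts, arbitrary order
  lab <- rep(names(sizes), sizes)[sample(n)]
  tt <- ifelse(lab == "trunk", runif(n, 0, 0.3), runif(n, 0.3, 1))
  global <- global_branching(tt, lab, 0.3)
  expr <- matrix(rnorm(2 * n), 2, n,
                 dimnames = list(c("g1", "g2"), global$cell_id))
  sub <- balanced_subsample(expr, global, 335, seed = 7)
  counts <- table(sub$global$label)
  expect_equal(sum(counts), 335)
  # the small stratum is retained up to the equal-allocation level
  expect_gte(unname(counts["2"]), 111)
  expect_lte(diff(range(counts)), 2)
  # a genuinely small stratum is kept whole and the rest rebalanced
  sub_small <- balanced_subsample(expr, global, 400, seed = 7)
  expect_equal(unname(table(sub_small$global$label)["2"]), 114)
  # branch-count spread can only shrink
  expect_lte(diff(range(counts)), diff(range(table(global$label))))
  # the identity case
  sub2 <- balanced_subsample(expr, global, n, seed = 7)
  expect_equal(ncol(sub2$expr), n)
})
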