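fast_config <- function(...) {
  args <- list(...)
  defaults <- list(n_candidates = 8, opt_maxit = 20, opt_maxit_warm = 6,
                   outer_max = 2, em_max = 20, inducing = 20)
  do.call(bgp_config, utils::modifyList(defaults, args))
}

small_branching_data <- function(n = 50, tb = 0.4, noise = 1e-3, seed = 101) {
  set.seed(seed)
  times <- sort(runif(n))
  memb <- sample(c("1", "2"), n, replace = TRUE)
  global <- global_branching(times, ifelse(times < tb, "trunk", memb), tb)
  gene <- sample_branching_gene(times, tb, memb, branching_kernel(2, 1.2),
                                noise_variance = noise)
  list(y = gene$y, global = global, tb = tb, gene = gene)
}

test_that("branching posterior is a stable softmax over candidate evidence", {
  expect_equal(branching_posterior(rep(-3, 5)), rep(0.2, 5))
  p <- branching_posterior(c(0, -1000, -1000))
  expect_gte(p[1], 1 - 1e-300)
  # frozen softmax values, verified by direct exponentiation by hand
  expect_equal(branching_posterior(c(0, -1, -2)),
               c(0.66524096, 0.24472847, 0.09003057), tolerance = 1e-7)
  # very large evidences do not overflow
  expect_equal(sum(branching_posterior(c(1e4, 1e4 - 1))), 1)
  # failed candidates receive zero mass
  expect_equal(branching_posterior(c(0, NA, 0)), c(0.5, 0, 0.5))
  expect_error(branching_posterior(c(NA, NA)), "-Inf or NA")
})

test_that("log Bayes factor averages grid evidence against no-branch", {
  expect_equal(bayes_factor(rep(-7.3, 6), -7.3), 0)
  expect_equal(bayes_factor(c(-10, -10), -12), 2)
  set.seed(7)
  le <- rnorm(10)
  shift <- 123.4
  expect_equal(bayes_factor(le + shift, -2 + shift),
               bayes_factor(le, -2), tolerance = 1e-10)
})

test_that("credible interval is the smallest contiguous covering window", {
  times <- seq(0.1, 1, by = 0.1)
  pm <- c(rep(0, 4), 1, rep(0, 5))
  expect_equal(unname(credible_interval(pm, times, 0.98)),
               c(0.5, 0.5))
  expect_equal(unname(credible_interval(rep(0.1, 10), times, 0.98)),
               c(0.1, 1.0))
  expect_equal(unname(credible_interval(c(0.5, 0.3, 0.2), 1:3, 0.75)),
               c(1, 2))
  # ties break toward earlier times
  expect_equal(unname(credible_interval(c(0.5, 0, 0.5), 1:3, 0.5)),
               c(1, 1))
})

test_that("fit_gene returns a coherent branching fit", {
  d <- small_branching_data(n = 50, tb = 0.4)
  fit <- fit_gene(d$y, d$global, fast_config(prior_confidence = 0.8),
                  gene_id = "g1")
  expect_s3_class(fit, "bgp_fit")
  expect_equal(sum(fit$posterior), 1, tolerance = 1e-12)
  expect_true(fit$map_time %in% fit$times)
  expect_lte(fit$credible_interval["lo"], fit$map_time)
  expect_gte(fit$credible_interval["hi"], fit$map_time)
  expect_equal(rowSums(fit$phi_map), rep(1, 50), tolerance = 1e-9)
  # low-noise branching gene: MAP near truth, branching strongly favoured
  expect_lt(abs(fit$map_time - d$tb), 0.15)
  expect_gt(fit$bayes_factor, 0)
  # evidence at the candidate nearest truth beats the no-branch model
  i_true <- which.min(abs(fit$times - d$tb))
  expect_gt(fit$log_evidence[i_true], fit$log_evidence_no_branch)
})

test_that("posterior over branching time is invariant to scaling y", {
  d <- small_branching_data(n = 40, tb = 0.5, seed = 103)
  cfg <- fast_config(prior_confidence = 0.8)
  f1 <- fit_gene(d$y, d$global, cfg)
  f2 <- fit_gene(5 * d$y, d$global, cfg)
  expect_equal(f1$map_time, f2$map_time)
  expect_equal(f1$posterior, f2$posterior, tolerance = 0.05)
  # optimised variances pick up the factor c^2 (to optimiser tolerance)
  expect_equal(f2$noise_var_map / f1$noise_var_map, 25, tolerance = 0.3)
  expect_equal(f2$kernel_map$signal_variance / f1$kernel_map$signal_variance,
               25, tolerance = 0.3)
})

test_that("predictive branch curves respect the intersection and prior limits", {
  d <- small_branching_data(n = 60, tb = 0.5, seed = 105)
  cfg <- fast_config(prior_confidence = 0.8)
  fit <- fit_gene(d$y, d$global, cfg)
  pred <- predict_branches(fit, d$y, d$global, c(fit$map_time, 0.98))
  at_bp <- pred[pred$t == fit$map_time, ]
  # the three latent means coincide at the fitted branching point
  expect_lt(diff(range(at_bp$mean)), 3 * sqrt(max(at_bp$var)) + 0.05)
  # far from the branching point the branch means separate (they fit
  # different cell subsets)
  far <- pred[pred$t > 0.9 & pred$branch != "trunk", ]
  expect_gt(abs(diff(far$mean)), 0.1)
})

test_that("predictive intervals approximately cover held-out observations", {
  set.seed(107)
  n <- 80
  times <- sort(runif(n))
  tb <- 0.4
  memb <- sample(c("1", "2"), n, replace = TRUE)
  global_all <- global_branching(times, ifelse(times < tb, "trunk", memb), tb)
  gene <- sample_branching_gene(times, tb, memb, branching_kernel(2, 1.2),
                                noise_variance = 0.05)
  hold <- seq(2, n, by = 4)
  train <- setdiff(seq_len(n), hold)
  gtrain <- global_branching(times[train],
                             ifelse(times[train] < tb, "trunk", memb[train]),
                             tb)
  fit <- fit_gene(gene$y[train], gtrain, fast_config(prior_confidence = 0.8))
  pred <- predict_branches(fit, gene$y[train], gtrain, times[hold])
  # evaluate each held-out cell against its own generating branch
  lab <- gene$cell_branch[hold]
  key <- ifelse(lab == "trunk", "trunk", lab)
  rows <- match(paste(times[hold], key),
                paste(pred$t, pred$branch))
  z <- (gene$y[hold] - pred$mean[rows]) /
    sqrt(pred$var[rows] + fit$noise_var_map)
  expect_gt(mean(abs(z) < 1.96), 0.80)
})

test_that("t-statistic prefilter matches the Welch formula and separates genes", {
  set.seed(109)
  n <- 60
  times <- sort(runif(n))
  memb <- rep(c("1", "2"), length.out = n)
  global <- global_branching(times, ifelse(times < 0.3, "trunk", memb), 0.3)
  flat <- rnorm(n)
  sep <- ifelse(memb == "1", 10, 0) + rnorm(n)
  expr <- rbind(flat = flat, sep = sep)
  res <- t_filter(expr, global, tail_fraction = 0.4, threshold = 3)
  expect_identical(res$keep, "sep")
  # statistic agrees with an independently coded Welch formula
  i1 <- which(global$label == "1")
  i1 <- i1[order(times[i1], decreasing = TRUE)][1:ceiling(0.4 * length(i1))]
  i2 <- which(global$label == "2")
  i2 <- i2[order(times[i2], decreasing = TRUE)][1:ceiling(0.4 * length(i2))]
  expect_equal(res$stats$t_stat[res$stats$gene_id == "sep"],
               oracle_welch_t(sep[i1], sep[i2]), tolerance = 1e-10)
})

test_that("fit_genes aligns cells by id and reports missing cells", {
  d <- small_branching_data(n = 30, tb = 0.5, seed = 111)
  expr <- matrix(d$y, 1, dimnames = list("g", d$global$cell_id))
  # shuffled columns give the same fit as the original order
  perm <- sample(ncol(expr))
  cfg <- fast_config(prior_confidence = 0.8, n_candidates = 5)
  f1 <- summary(fit_genes(expr, d$global, cfg))
  f2 <- summary(fit_genes(expr[, perm, drop = FALSE], d$global, cfg))
  expect_equal(f1$map_time, f2$map_time, tolerance = 1e-9)
  colnames(expr)[2] <- "missing_cell"
  expect_error(fit_genes(expr, d$global, cfg), "missing_cell")
})
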