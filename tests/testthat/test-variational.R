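make_global <- function(times, tb, seed = 1) {
  set.seed(seed)
  lab <- ifelse(times < tb, "trunk", sample(c("1", "2"), length(times),
                                            replace = TRUE))
  global_branching(times, lab, tb)
}

test_that("assignment prior encodes trunk, informative and uninformative rows", {
  times <- c(0.1, 0.25, 0.6, 0.8)
  global <- global_branching(times, c("trunk", "trunk", "1", "2"), 0.3)
  # candidate at the global branching time, 0.99 confidence
  pi <- assignment_prior(global, 0.3, 0.99)
  expect_equal(pi[1, ], c(1, 0, 0))        # before the candidate: trunk only
  expect_equal(pi[3, ], c(0, 0.99, 0.01))  # globally on branch 1
  expect_equal(pi[4, ], c(0, 0.01, 0.99))  # globally on branch 2
  # simulation-study confidence of 0.80
  pi80 <- assignment_prior(global, 0.3, 0.80)
  expect_equal(pi80[3, ], c(0, 0.80, 0.20))
  # early candidate: cells between candidate and global time are uninformative
  pi_early <- assignment_prior(global, 0.2, 0.99)
  expect_equal(pi_early[2, ], c(0, 0.5, 0.5))
  expect_true(all(abs(rowSums(pi_early) - 1) < 1e-12))
  # all-trunk prior for the non-branching model
  expect_equal(assignment_prior(global, Inf, 0.99),
               cbind(rep(1, 4), 0, 0))
  expect_error(assignment_prior(global, 0.3, 0.3), "confidence")
  expect_error(assignment_prior(global, 0.3, 1), "confidence")
})

test_that("assignment KL matches the double-sum oracle and its identities", {
  expect_equal(assignment_kl(cbind(1, 0, 0), cbind(1, 0, 0)), 0)
  phi1 <- matrix(c(0, 1, 0), 1)
  pi1 <- matrix(c(0, 0.5, 0.5), 1)
  expect_equal(assignment_kl(phi1, pi1), log(2), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:5) {
    phi <- matrix(rexp(15), 5)
    phi <- phi / rowSums(phi)
    pi <- matrix(rexp(15), 5)
    pi <- pi / rowSums(pi)
    expect_equal(assignment_kl(phi, pi), oracle_kl(phi, pi),
                 tolerance = 1e-12)
    expect_gte(assignment_kl(phi, pi), 0)
  }
  expect_error(assignment_kl(phi1, matrix(c(0.5, 0, 0.5), 1)), "infinite KL")
})

test_that("degenerate one-function bound equals the exact GP log marginal", {
  set.seed(41)
  n <- 15
  times <- sort(runif(n))
  global <- make_global(times, 0.5)
  y <- rnorm(n)
  y <- y - mean(y)
  kern <- branching_kernel(2, 1.2, Inf)
  prior <- assignment_prior(global, Inf)
  b <- collapsed_bound(y, times, prior, kern, 0.3, prior)
  Kff <- se_cov(times, times, 2, 1.2) + diag(1e-6 * 2, n)
  expect_equal(b, oracle_logmvn(y, Kff + diag(0.3, n)), tolerance = 1e-9)
})

test_that("collapsed bound never exceeds the enumeration oracle (small cases)", {
  set.seed(51)
  for (i in 1:10) {
    inst <- random_instance(n = 6)
    opt <- optimise_phi(inst)
    exact <- oracle_exact_evidence(inst$y, inst$times, inst$tb, inst$kernel,
                                   inst$noise_var, inst$prior)
    expect_lte(opt$bound, exact + 1e-8)
  }
})

test_that("bound gap closes for well-separated branches at low noise", {
  # construct widely separated branches so the posterior over Z is
  # near-deterministic and the mean-field bound becomes tight
  times <- c(0.1, 0.3, 0.6, 0.7, 0.8, 0.9)
  tb <- 0.5
  global <- global_branching(times, c("trunk", "trunk", "1", "2", "1", "2"),
                             tb)
  y <- c(0, 0, 3, -3, 3.5, -3.5)
  y <- y - mean(y)
  inst <- list(y = y, times = times, tb = tb,
               kernel = branching_kernel(4, 0.6, tb), noise_var = 1e-3,
               prior = assignment_prior(global, tb, 0.8))
  opt <- optimise_phi(inst)
  exact <- oracle_exact_evidence(y, times, tb, inst$kernel, inst$noise_var,
                                 inst$prior)
  expect_lte(opt$bound, exact + 1e-8)
  expect_lt(exact - opt$bound, 0.01)
})

test_that("zero-data bound splits into its determinant terms", {
  set.seed(61)
  n <- 8
  times <- sort(runif(n))
  global <- make_global(times, 0.4)
  kern <- branching_kernel(1.5, 0.8, 0.4)
  prior <- assignment_prior(global, 0.4, 0.8)
  y0 <- rep(0, n)
  for (s2 in c(0.1, 0.2)) {
    b <- collapsed_bound(y0, times, prior, kern, s2, prior)
    # independent evaluation: -N/2 log(2 pi s2) - 1/2 log|I + S K S| with
    # the determinant from base R's determinant() on the support
    s <- which(as.vector(prior) > 0)
    x <- branchgp:::aug_full(times)
    K <- branchgp:::bgp_cov_jittered(kern, times)[s, s]
    S <- sqrt(as.vector(prior)[s] / s2)
    B <- diag(length(s)) + t(K * S) * S
    expect_equal(b, -n / 2 * log(2 * pi * s2) -
                   0.5 * as.numeric(determinant(B)$modulus),
                 tolerance = 1e-8)
  }
})

test_that("mean-field updates are monotone in the collapsed bound", {
  set.seed(71)
  inst <- random_instance(n = 12)
  phi <- inst$prior
  s <- which(as.vector(inst$prior) > 0)
  mats <- branchgp:::bgp_mats(inst$kernel, inst$times, s)
  prev <- -Inf
  for (i in 1:25) {
    phi <- branchgp:::bgp_phi_update(inst$y, phi, inst$prior,
                                     inst$noise_var, mats)
    b <- branchgp:::bgp_bound_mats(inst$y, phi, inst$prior, inst$noise_var,
                                   mats)
    expect_gte(b, prev - 1e-8)
    prev <- b
  }
  # posterior support never escapes the prior support
  expect_true(all(phi[inst$prior == 0] == 0))
  expect_equal(rowSums(phi), rep(1, 12), tolerance = 1e-12)
})

test_that("fitted assignments recover well-separated branch memberships", {
  set.seed(81)
  n <- 60
  times <- sort(runif(n))
  tb <- 0.3
  memb <- sample(c("1", "2"), n, replace = TRUE)
  global <- global_branching(times, ifelse(times < tb, "trunk", memb), tb)
  gene <- sample_branching_gene(times, tb, memb,
                                branching_kernel(2, 1.2),
                                noise_variance = 1e-3)
  cfg <- bgp_config(prior_confidence = 0.8, inducing = 0)
  fit <- fit_branch_model(gene$y, times, global, tb, cfg)
  far <- which(times > tb + 0.2)
  truth_col <- ifelse(gene$cell_branch[far] == "1", 2L, 3L)
  recovered <- fit$phi[cbind(far, truth_col)]
  expect_gt(mean(recovered > 0.95), 0.9)
  # optimisation trace is non-decreasing
  expect_true(all(diff(fit$trace) >= -1e-6))
})

test_that("a pure-noise gene collapses to an iid Gaussian fit", {
  set.seed(91)
  n <- 50
  times <- sort(runif(n))
  global <- make_global(times, 0.4)
  y <- rnorm(n, sd = 0.3)
  cfg <- bgp_config(inducing = 0)
  fit <- fit_branch_model(y, times, global, Inf, cfg)
  yc <- y - mean(y)
  iid <- sum(dnorm(yc, 0, sd(yc), log = TRUE))
  expect_lt(abs(fit$bound - iid), 3)
  expect_lt(fit$kernel$signal_variance, var(y))
})
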