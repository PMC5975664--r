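# Independent oracle routines used across the suite. These deliberately
# avoid the package's own linear-algebra paths.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Multivariate normal log density via a plain Cholesky factorisation.
oracle_logmvn <- function(y, K) {
  U <- chol(K)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(U))) -
    0.5 * sum(forwardsolve(t(U), y)^2)
}

# Exact log marginal likelihood by full enumeration of the assignment
# indicator Z: cells before the candidate branching time are trunk, every
# post-branch cell ranges over both branches.
oracle_exact_evidence <- function(y, times, branch_time, kernel, noise_var,
                                  prior) {
  n <- length(y)
  K3 <- branchgp:::bgp_cov_jittered(kernel, times)
  post <- which(times >= branch_time)
  combos <- expand.grid(rep(list(2:3), length(post)))
  if (!nrow(combos)) combos <- data.frame(row.names = 1)
  terms <- vapply(seq_len(nrow(combos)), function(ci) {
    fidx <- rep(1L, n)
    if (length(post)) fidx[post] <- as.integer(unlist(combos[ci, ]))
    jj <- (fidx - 1L) * n + seq_len(n)
    lp <- sum(log(prior[cbind(seq_len(n), fidx)]))
    lp + oracle_logmvn(y, K3[jj, jj] + diag(noise_var, n))
  }, numeric(1))
  logsumexp(terms)
}

# Double-loop KL sum, Welch t and all-pairs AUC / ordering oracles.
oracle_kl <- function(phi, prior) {
  tot <- 0
  for (i in seq_len(nrow(phi))) {
    for (j in seq_len(ncol(phi))) {
      if (phi[i, j] > 0) {
        tot <- tot + phi[i, j] * log(phi[i, j] / prior[i, j])
      }
    }
  }
  tot
}

oracle_welch_t <- function(x1, x2) {
  (mean(x1) - mean(x2)) /
    sqrt(var(x1) / length(x1) + var(x2) / length(x2))
}

oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

oracle_prob_before <- function(a, b) {
  mean(outer(a, b, "<"))
}

# Small random branching instance shared by the bound property tests.
random_instance <- function(n = 6, n_assignable = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- sort(runif(n))
  tb <- runif(1, 0.3, 0.7)
  if (!is.null(n_assignable)) {
    # force exactly n_assignable cells after the branching point
    times <- sort(c(runif(n - n_assignable, 0, tb - 1e-3),
                    runif(n_assignable, tb + 1e-3, 1)))
  }
  lab <- ifelse(times < tb, "trunk", sample(c("1", "2"), n, replace = TRUE))
  global <- global_branching(times, lab, tb)
  kernel <- branching_kernel(exp(runif(1, -0.7, 0.7)),
                             runif(1, 0.3, 1.5), tb)
  noise_var <- runif(1, 0.05, 0.5)
  prior <- assignment_prior(global, tb, runif(1, 0.6, 0.95))
  y <- rnorm(n)
  y <- y - mean(y)
  list(y = y, times = times, tb = tb, global = global, kernel = kernel,
       noise_var = noise_var, prior = prior)
}

# EM-optimised assignment posterior at fixed hyperparameters.
optimise_phi <- function(inst, iters = 100) {
  phi <- inst$prior
  s <- which(as.vector(inst$prior) > 0)
  mats <- branchgp:::bgp_mats(inst$kernel, inst$times, s)
  for (i in seq_len(iters)) {
    phi <- branchgp:::bgp_phi_update(inst$y, phi, inst$prior,
                                     inst$noise_var, mats)
  }
  list(phi = phi,
       bound = branchgp:::bgp_bound_mats(inst$y, phi, inst$prior,
                                         inst$noise_var, mats))
}
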