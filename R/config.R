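#' Run configuration
#'
#' Collects the tunable settings of a branching-model run. Defaults follow
#' the package's standard analysis: a 20-point candidate grid on the central
#' 90% of the pseudotime range, a 0.99 prior assignment confidence, 30
#' inducing points (sparse inference engages automatically once the expanded
#' representation exceeds three times the inducing count), 98% credible
#' intervals and 5000 posterior samples for downstream summaries.
#'
#' @param n_candidates Size of the candidate branching-time grid
#'   (\eqn{N_b \ge 2}).
#' @param prior_confidence Prior assignment probability in \code{[0.5, 1)};
#'   0.5 disables the informative prior.
#' @param inducing Number of inducing pseudotimes \eqn{k}; 0 forces full
#'   inference.
#' @param credible_level Credible-interval mass, in (0, 1).
#' @param n_samples Posterior samples \eqn{S} for downstream analyses.
#' @param network_confidence Edge confidence cut-off of the branch-order
#'   network.
#' @param evidence_cutoff Log-Bayes-factor threshold used to select genes for
#'   downstream analyses.
#' @param seed Master seed for any stochastic stage.
#' @param em_max,em_tol Cap and mean-absolute-change tolerance of the
#'   mean-field assignment updates.
#' @param outer_max,outer_tol Cap and bound-change tolerance of the outer
#'   (assignments / hyperparameters) loop.
#' @param opt_maxit,opt_maxit_warm L-BFGS-B iteration caps for cold and
#'   warm-started hyperparameter fits.
#' @param jitter Relative diagonal jitter added before factorisations.
#' @param noise_floor_frac Lower bound on the noise variance as a fraction of
#'   the sample variance, preventing degenerate likelihood spikes.
#' @return An object of class \code{bgp_config} (a validated list).
#' @export
bgp_config <- function(n_candidates = 20, prior_confidence = 0.99,
                       inducing = 30, credible_level = 0.98,
                       n_samples = 5000, network_confidence = 0.95,
                       evidence_cutoff = 0, seed = 1,
                       em_max = 30, em_tol = 1e-4,
                       outer_max = 3, outer_tol = 1e-3,
                       opt_maxit = 40, opt_maxit_warm = 8,
                       jitter = 1e-6, noise_floor_frac = 1e-6) {
  if (n_candidates < 2) stop("'n_candidates' must be at least 2")
  if (prior_confidence < 0.5 || prior_confidence >= 1) {
    stop("'prior_confidence' must lie in [0.5, 1)")
  }
  if (inducing < 0) stop("'inducing' must be non-negative")
  if (credible_level <= 0 || credible_level >= 1) {
    stop("'credible_level' must lie in (0, 1)")
  }
  if (network_confidence <= 0 || network_confidence > 1) {
    stop("'network_confidence' must lie in (0, 1]")
  }
  if (n_samples < 1) stop("'n_samples' must be positive")
  if (jitter <= 0 || noise_floor_frac <= 0) {
    stop("'jitter' and 'noise_floor_frac' must be positive")
  }
  structure(
    list(n_candidates = as.integer(n_candidates),
         prior_confidence = prior_confidence,
         inducing = as.integer(inducing),
         credible_level = credible_level,
         n_samples = as.integer(n_samples),
         network_confidence = network_confidence,
         evidence_cutoff = evidence_cutoff,
         seed = as.integer(seed),
         em_max = as.integer(em_max), em_tol = em_tol,
         outer_max = as.integer(outer_max), outer_tol = outer_tol,
         opt_maxit = as.integer(opt_maxit),
         opt_maxit_warm = as.integer(opt_maxit_warm),
         jitter = jitter, noise_floor_frac = noise_floor_frac),
    class = "bgp_config"
  )
}

#' @export
print.bgp_config <- function(x, ...) {
  cat("branchgp run configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
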