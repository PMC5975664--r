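#' Squared-exponential covariance
#'
#' Evaluates the squared-exponential (RBF) kernel
#' \eqn{K(t, t') = \sigma^2 \exp\{-(t - t')^2 / (2\lambda^2)\}} between two
#' pseudotime vectors. This is the base kernel shared by the trunk and both
#' branch latent functions of the branching model.
#'
#' @param t1,t2 Numeric vectors of pseudotimes.
#' @param variance Signal variance \eqn{\sigma^2} (expression units squared);
#'   must be positive. On the diagonal \code{K(t, t) = variance}.
#' @param lengthscale Kernel lengthscale \eqn{\lambda} in pseudotime units;
#'   must be positive.
#' @return A \code{length(t1)} by \code{length(t2)} covariance matrix.
#' @examples
#' se_cov(0.5, 0.5, variance = 2, lengthscale = 1.2)  # == 2
#' @export
se_cov <- function(t1, t2, variance, lengthscale) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0) {
    stop("'variance' must be a positive finite scalar")
  }
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0) {
    stop("'lengthscale' must be a positive finite scalar")
  }
  if (anyNA(t1) || anyNA(t2)) stop("pseudotimes must be finite")
  d <- outer(t1, t2, "-")
  variance * exp(-0.5 * (d / lengthscale)^2)
}

#' Branching kernel specification
#'
#' Bundles the hyperparameters of the branching Gaussian process kernel: the
#' base-kernel signal variance and lengthscale, and the branching point
#' \code{branch_point} at which the trunk and the two branch latent functions
#' are constrained to intersect. \code{branch_point = Inf} is the no-branch
#' sentinel: the cross-covariance between distinct latent functions vanishes
#' and the three functions become independent (the overlapping-mixture limit),
#' which is how the non-branching model is represented.
#'
#' @param signal_variance Positive scalar, marginal variance of each latent
#'   function.
#' @param lengthscale Positive scalar, in pseudotime units.
#' @param branch_point Branching pseudotime \eqn{t_b}; a finite number or
#'   \code{Inf} (no branching).
#' @param base_kernel Base kernel family; only \code{"se"}
#'   (squared exponential) is currently implemented.
#' @return An object of class \code{bgp_kernel}.
#' @export
branching_kernel <- function(signal_variance = 2, lengthscale = 1.2,
                             branch_point = Inf, base_kernel = c("se")) {
  base_kernel <- match.arg(base_kernel)
  if (!is.numeric(signal_variance) || length(signal_variance) != 1L ||
      !is.finite(signal_variance) || signal_variance <= 0) {
    stop("'signal_variance' must be a positive finite scalar")
  }
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0) {
    stop("'lengthscale' must be a positive finite scalar")
  }
  if (!is.numeric(branch_point) || length(branch_point) != 1L ||
      is.na(branch_point)) {
    stop("'branch_point' must be a single number (Inf for no branching)")
  }
  structure(
    list(signal_variance = signal_variance, lengthscale = lengthscale,
         branch_point = branch_point, base_kernel = base_kernel),
    class = "bgp_kernel"
  )
}

#' @export
print.bgp_kernel <- function(x, ...) {
  bp <- if (is.infinite(x$branch_point)) "no branch" else
    format(x$branch_point, digits = 4)
  cat(sprintf(
    "Branching GP kernel (%s): signal variance %.4g, lengthscale %.4g, branch point %s\n",
    x$base_kernel, x$signal_variance, x$lengthscale, bp))
  invisible(x)
}

# Augmented input: every cell is represented once per latent function
# (1 = trunk, 2/3 = branches), giving an expanded set of size 3N.
aug_input <- function(times, labels) {
  if (anyNA(times) || any(!is.finite(times))) stop("pseudotimes must be finite")
  if (!all(labels %in% 1:3)) stop("function labels must be in {1, 2, 3}")
  if (length(times) != length(labels)) stop("times and labels differ in length")
  list(t = as.numeric(times), f = as.integer(labels))
}

aug_full <- function(times) {
  aug_input(rep(times, 3L), rep(1:3, each = length(times)))
}

#' Branching-kernel covariance over augmented inputs
#'
#' Covariance of the three latent functions (trunk and two branches, sharing
#' one base kernel) constrained to intersect at the branching point
#' \eqn{t_b}. Entries between points on the same latent function equal the
#' base kernel \eqn{K(t, t')}; entries between different latent functions
#' equal \eqn{K(t, t_b) K(t_b, t') / K(t_b, t_b)}. The constraint forces
#' \eqn{\mathrm{Var}[f(t_b) - g(t_b)] = 0}, and as \eqn{t_b} moves far beyond
#' the data the cross-blocks decay to zero, recovering independent latent
#' functions.
#'
#' @param kernel A \code{\link{branching_kernel}} specification.
#' @param t1,t2 Pseudotime vectors.
#' @param f1,f2 Integer latent-function labels in \code{{1, 2, 3}} (1 = trunk).
#' @return The \code{length(t1)} by \code{length(t2)} covariance matrix
#'   (no jitter added).
#' @export
branching_cov <- function(kernel, t1, f1, t2 = t1, f2 = f1) {
  stopifnot(inherits(kernel, "bgp_kernel"))
  x <- aug_input(t1, f1)
  y <- aug_input(t2, f2)
  v <- kernel$signal_variance
  l <- kernel$lengthscale
  tp <- kernel$branch_point
  K <- se_cov(x$t, y$t, v, l)
  if (is.infinite(tp)) {
    cross <- matrix(0, length(x$t), length(y$t))
  } else {
    ktp <- v  # K(tp, tp) for the squared-exponential base kernel
    if (ktp <= 0) stop("degenerate base kernel: K(t_b, t_b) = 0")
    cross <- tcrossprod(se_cov(x$t, tp, v, l), se_cov(y$t, tp, v, l)) / ktp
  }
  same <- outer(x$f, y$f, "==")
  out <- cross
  out[same] <- K[same]
  out
}

# Square covariance over the full augmented grid with diagonal jitter
# (1e-6 * signal variance by default) to keep Cholesky factorisations stable.
bgp_cov_jittered <- function(kernel, times, jitter = 1e-6) {
  x <- aug_full(times)
  K <- branching_cov(kernel, x$t, x$f)
  diag(K) <- diag(K) + jitter * kernel$signal_variance
  K
}

#' Sample latent functions from the constrained branching prior
#'
#' Draws joint samples of (trunk, branch 1, branch 2) from the branching GP
#' prior at the supplied pseudotimes. Used by the synthetic-data generator and
#' for Monte-Carlo checks of the kernel law.
#'
#' @param kernel A \code{\link{branching_kernel}}.
#' @param times Pseudotime vector of length N.
#' @param n_draws Number of joint draws.
#' @param jitter Relative diagonal jitter.
#' @return An \code{n_draws} by \code{3N} matrix; columns are ordered trunk
#'   values, then branch-1, then branch-2 values at \code{times}.
#' @export
draw_branching_gp <- function(kernel, times, n_draws = 1, jitter = 1e-6) {
  K <- bgp_cov_jittered(kernel, times, jitter)
  U <- chol(K)
  Z <- matrix(stats::rnorm(n_draws * nrow(K)), n_draws, nrow(K))
  Z %*% U
}
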