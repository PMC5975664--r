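#' Assignment prior for a candidate branching time
#'
#' Builds the N x 3 row-stochastic categorical prior \eqn{\Pi} over latent
#' functions (trunk, branch 1, branch 2) for one candidate branching time:
#' \itemize{
#'   \item cells before the candidate time are deterministically trunk,
#'     \code{(1, 0, 0)} — only one latent function exists there;
#'   \item cells at/after both the candidate time and the global branching
#'     time get \code{(0, c, 1 - c)} or \code{(0, 1 - c, c)} according to
#'     their global label, with \code{c = confidence};
#'   \item cells after the candidate time but before the global branching
#'     time (possible for early candidates) have no global label and get the
#'     uninformative \code{(0, 0.5, 0.5)}, as do post-branch cells still
#'     labelled trunk.
#' }
#' \code{confidence = 0.5} gives the fully uninformative prior used by the
#' "no prior" mode of the benchmark.
#'
#' @param global A \code{\link{global_branching}} object.
#' @param candidate_time Candidate branching time (same scale as
#'   \code{global$pseudotime}); \code{Inf} yields the all-trunk prior of the
#'   non-branching model.
#' @param confidence Prior assignment probability \code{c} in
#'   \code{[0.5, 1)}; 0.99 is the default used on real data.
#' @return An N x 3 matrix with rows summing to 1.
#' @export
assignment_prior <- function(global, candidate_time, confidence = 0.99) {
  stopifnot(inherits(global, "global_branching"))
  if (!is.numeric(confidence) || length(confidence) != 1L ||
      confidence < 0.5 || confidence >= 1) {
    stop("'confidence' must lie in [0.5, 1)")
  }
  t <- global$pseudotime
  n <- length(t)
  pi <- matrix(0, n, 3)
  pre <- t < candidate_time
  pi[pre, 1] <- 1
  mid <- !pre & t < global$branch_time
  pi[mid, 2:3] <- 0.5
  post <- !pre & !mid
  lab <- as.character(global$label)
  b1 <- post & lab == "1"
  b2 <- post & lab == "2"
  btr <- post & lab == "trunk"
  pi[b1, 2] <- confidence
  pi[b1, 3] <- 1 - confidence
  pi[b2, 2] <- 1 - confidence
  pi[b2, 3] <- confidence
  pi[btr, 2:3] <- 0.5
  pi
}

#' KL divergence between assignment posteriors and the prior
#'
#' Computes \eqn{\sum_{n,m} \Phi_{nm} \log(\Phi_{nm} / \Pi_{nm})} with the
#' convention \eqn{0 \log 0 = 0}. Positive posterior mass where the prior is
#' zero would make the divergence infinite and is reported as an error.
#'
#' @param phi N x 3 row-stochastic matrix of posterior assignment
#'   probabilities.
#' @param prior N x 3 row-stochastic prior matrix.
#' @return A non-negative scalar.
#' @export
assignment_kl <- function(phi, prior) {
  if (!all(dim(phi) == dim(prior))) stop("phi and prior dimensions differ")
  if (any(phi > 1e-12 & prior == 0)) {
    stop("infinite KL: positive posterior mass where the prior is zero")
  }
  i <- phi > 0 & prior > 0
  sum(phi[i] * log(phi[i] / prior[i]))
}

# --- internal: precomputed kernel matrices for one (kernel, grid) pair -----
#
# The collapsed bound works on the expanded representation of size M = 3N:
# each cell appears once per latent function (column-major over phi), A is
# the M x M diagonal holding the phi entries, and Phi'Y has entries
# phi[n, m] * y[n]. Because phi is supported only where the prior is
# positive, all linear algebra is restricted to the prior's support
# `s` (expanded indices), which is exact. `inducing_times` switches to the
# sparse (Nystrom) matrices; inducing locations are replicated across the
# three labels. The diagonal jitter is treated as a white-noise kernel
# component, so cross-covariances between coinciding (pseudotime, label)
# pairs carry it too; this makes the sparse bound with inducing set = data
# set agree exactly with the full bound.
bgp_mats <- function(kernel, times, s = NULL, inducing_times = NULL,
                     jitter = 1e-6, geom = NULL) {
  n <- length(times)
  if (is.null(s)) s <- seq_len(3L * n)
  if (is.null(geom)) {
    geom <- bgp_geom(kernel$branch_point, times, s, inducing_times)
  }
  jit <- jitter * kernel$signal_variance
  v <- kernel$signal_variance
  il2 <- -0.5 / kernel$lengthscale^2
  if (is.null(inducing_times)) {
    K <- v * exp(il2 * geom$xx)
    diag(K) <- diag(K) + jit
    list(sparse = FALSE, n = n, s = s, K = K, Kdiag = diag(K))
  } else {
    Kuu <- v * exp(il2 * geom$uu)
    diag(Kuu) <- diag(Kuu) + jit
    Kux <- v * exp(il2 * geom$ux)
    Kux[geom$hit] <- Kux[geom$hit] + jit
    Lu <- chol(Kuu)                      # upper: Kuu = Lu' Lu
    V <- forwardsolve(t(Lu), Kux)        # Lu^-T Kux, so Q = V'V
    list(sparse = TRUE, n = n, s = s, Lu = Lu, Kux = Kux, V = V,
         Qdiag = colSums(V^2),
         Kdiag = rep(v + jit, length(s)))
  }
}

# Hyperparameter-free geometry of the branching kernel: every covariance
# entry is sv * exp(-0.5 * D2 / ls^2) with D2 the squared distance taken
# directly for same-label pairs and through the branching point for
# cross-label pairs, so D2 can be cached across hyperparameter evaluations.
# `hit` marks exactly coinciding (pseudotime, label) inducing/data pairs,
# which share the white-noise jitter component.
bgp_geom <- function(branch_point, times, s, inducing_times = NULL) {
  x <- aug_full(times)
  xs <- list(t = x$t[s], f = x$f[s])
  d2 <- function(a, b) {
    D <- outer((a$t - branch_point)^2, (b$t - branch_point)^2, "+")
    same <- outer(a$f, b$f, "==")
    D[same] <- (outer(a$t, b$t, "-")^2)[same]
    D
  }
  if (is.null(inducing_times)) {
    list(xx = d2(xs, xs))
  } else {
    u <- aug_full(inducing_times)
    list(uu = d2(u, u), ux = d2(u, xs),
         hit = outer(u$t, xs$t, "==") & outer(u$f, xs$f, "=="))
  }
}

# --- internal: collapsed bound given precomputed matrices ------------------
#
# Stable pseudo-observation form. On the prior support, the expanded
# pseudo-datum at index j is the cell's own value y_n with weight a_j =
# phi_j, so with S = sqrt(a)/sigma and e = S * y the bound's GP part is
#   -(N/2) log(2 pi s2) - (Y'Y - sum a y^2) / (2 s2)
#   - 1/2 log|I + S K S| - 1/2 e' (I + S K S)^-1 e
# which involves nothing larger than O(1/sigma^2) and no differences of
# sigma^-4-scaled quantities (the naive evaluation of the collapsed bound
# loses all precision when the noise variance is small).
bgp_bound_mats <- function(y, phi, prior, noise_var, mats) {
  n <- mats$n
  s2 <- noise_var
  s <- mats$s
  a <- as.vector(phi)[s]
  ys <- rep(y, 3L)[s]
  S <- sqrt(a / s2)
  e <- S * ys
  kl <- assignment_kl(phi, prior)
  const <- -n / 2 * log(2 * pi * s2) -
    (sum(y^2) - sum(a * ys^2)) / (2 * s2)
  if (!mats$sparse) {
    SK <- mats$K * S                     # row-scaled: diag(S) K
    B <- SK * rep(S, each = nrow(SK))    # S K S
    diag(B) <- diag(B) + 1
    cholB <- chol(B)
    logdet <- 2 * sum(log(diag(cholB)))
    q <- forwardsolve(t(cholB), e)       # e' B^-1 e = |q|^2
    const - 0.5 * logdet - 0.5 * sum(q^2) - kl
  } else {
    V <- mats$V
    Vs <- V * rep(S, each = nrow(V))     # column-scaled: V diag(S)
    B <- tcrossprod(Vs)
    diag(B) <- diag(B) + 1
    cholB <- chol(B)
    logdet <- 2 * sum(log(diag(cholB)))
    w <- as.vector(Vs %*% e)
    z <- forwardsolve(t(cholB), w)
    quad <- -0.5 * (sum(e^2) - sum(z^2))
    trace_corr <- sum(a * pmax(mats$Kdiag - mats$Qdiag, 0)) / (2 * s2)
    const - 0.5 * logdet + quad - trace_corr - kl
  }
}

#' Collapsed variational bound (full inference)
#'
#' Evaluates the collapsed evidence lower bound of the branching model after
#' the latent GP functions have been integrated out analytically:
#' \deqn{L_2 = -\tfrac{N}{2}\log(2\pi\sigma^2) - \tfrac{Y'Y}{2\sigma^2}
#'   - \tfrac12 \log|K| - \tfrac12 \log|A\sigma^{-2} + K^{-1}|
#'   + \tfrac12 \sigma^{-4} Y'\Phi (A\sigma^{-2} + K^{-1})^{-1} \Phi'Y
#'   - \mathrm{KL}[q(Z)\,\|\,p(Z)]}
#' computed via Cholesky factorisations of \eqn{I + S K S} (with
#' \eqn{S = A^{1/2}/\sigma}) so that \eqn{K^{-1}} is never formed. When all
#' assignment mass sits on a single latent function and the prior agrees,
#' the bound equals the exact Gaussian-process log marginal likelihood.
#'
#' @param y Centred expression vector of length N.
#' @param times Pseudotime vector of length N.
#' @param phi N x 3 posterior assignment probabilities.
#' @param kernel A \code{\link{branching_kernel}} with the candidate
#'   branching point.
#' @param noise_var Observation noise variance \eqn{\sigma^2 > 0}.
#' @param prior N x 3 assignment prior (see \code{\link{assignment_prior}}).
#' @param jitter Relative diagonal jitter.
#' @return The scalar bound value (a lower bound on \eqn{\log p(Y)}).
#' @export
collapsed_bound <- function(y, times, phi, kernel, noise_var, prior,
                            jitter = 1e-6) {
  check_state(y, times, phi, prior, noise_var)
  s <- which(as.vector(prior) > 0)
  bgp_bound_mats(y, phi, prior, noise_var,
                 bgp_mats(kernel, times, s, NULL, jitter))
}

#' Sparse collapsed bound (inducing-point inference)
#'
#' Titsias-style collapsed bound in which the full kernel matrix is replaced
#' by the Nystrom approximation \eqn{Q = K_{xu} K_{uu}^{-1} K_{ux}} inside
#' \code{\link{collapsed_bound}} and the trace correction
#' \eqn{\mathrm{tr}[A (K - Q)] / (2\sigma^2)} is subtracted, with the
#' assignment expectations \eqn{A} weighting the correction. Cost is
#' \eqn{O(k^2 N)} for \eqn{k} inducing points. With the inducing set equal to
#' the full input set the bound coincides with the full collapsed bound; for
#' proper subsets it can only be lower at shared parameters.
#'
#' @inheritParams collapsed_bound
#' @param inducing_times Pseudotimes of the inducing points (replicated
#'   internally across the three latent-function labels).
#' @return The scalar sparse bound value.
#' @export
sparse_collapsed_bound <- function(y, times, phi, kernel, noise_var, prior,
                                   inducing_times, jitter = 1e-6) {
  check_state(y, times, phi, prior, noise_var)
  if (!length(inducing_times)) stop("need at least one inducing point")
  s <- which(as.vector(prior) > 0)
  mats <- tryCatch(
    bgp_mats(kernel, times, s, inducing_times, jitter),
    error = function(e) {
      bgp_mats(kernel, times, s, inducing_times, jitter * 100)
    }
  )
  bgp_bound_mats(y, phi, prior, noise_var, mats)
}

check_state <- function(y, times, phi, prior, noise_var) {
  n <- length(y)
  if (length(times) != n) stop("y and times differ in length")
  if (!is.matrix(phi) || nrow(phi) != n || ncol(phi) != 3L) {
    stop("phi must be an N x 3 matrix")
  }
  if (!is.matrix(prior) || nrow(prior) != n || ncol(prior) != 3L) {
    stop("prior must be an N x 3 matrix")
  }
  if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var <= 0) {
    stop("'noise_var' must be a positive scalar")
  }
  if (any(abs(rowSums(phi) - 1) > 1e-8)) stop("phi rows must sum to 1")
  invisible(TRUE)
}

# --- internal: moments of the optimal q(F) on the prior support ------------
#
# q(F) is the GP posterior under the assignment-weighted likelihood:
# precision K^-1 + A/sigma^2, mean Sigma Phi'Y / sigma^2. Returns the mean
# and marginal variance at the supported expanded points (marginals at
# unweighted points are not needed by the assignment update).
bgp_qmoments <- function(y, phi, noise_var, mats) {
  s2 <- noise_var
  s <- mats$s
  a <- as.vector(phi)[s]
  r <- (as.vector(phi) * rep(y, 3L))[s]
  S <- sqrt(a / s2)
  if (!mats$sparse) {
    SK <- mats$K * S
    B <- SK * rep(S, each = nrow(SK))
    diag(B) <- diag(B) + 1
    cholB <- chol(B)
    T1 <- forwardsolve(t(cholB), SK)
    vr <- pmax(mats$Kdiag - colSums(T1^2), 1e-12)
    m <- (as.vector(mats$K %*% r) -
            as.vector(crossprod(T1, T1 %*% r))) / s2
    list(mean = m, var = vr)
  } else {
    Kux <- mats$Kux
    Ka <- Kux * rep(a, each = nrow(Kux))
    Lam <- tcrossprod(Ka, Kux) / s2 + crossprod(mats$Lu)
    cholL <- chol(Lam)
    H <- forwardsolve(t(cholL), Kux)
    m <- as.vector(crossprod(H, H %*% r)) / s2
    vr <- pmax(mats$Kdiag - mats$Qdiag, 0) + colSums(H^2)
    list(mean = m, var = pmax(vr, 1e-12))
  }
}

# --- internal: exact mean-field update of the assignment posterior ---------
#
# Given q(F) moments, the optimal phi row is the softmax of
# log Pi_nm - (E[f^2] - 2 y_n E[f]) / (2 sigma^2) over the prior support.
# This is exact coordinate ascent on the (collapsed) bound.
bgp_phi_update <- function(y, phi, prior, noise_var, mats) {
  qm <- bgp_qmoments(y, phi, noise_var, mats)
  n <- mats$n
  M3 <- matrix(0, n, 3)
  V3 <- matrix(0, n, 3)
  M3[mats$s] <- qm$mean
  V3[mats$s] <- qm$var
  LP <- -(M3^2 + V3 - 2 * y * M3) / (2 * noise_var)
  LP <- LP + log(prior)
  LP[prior == 0] <- -Inf
  mx <- pmax(LP[, 1], LP[, 2], LP[, 3])
  P <- exp(LP - mx)
  P / rowSums(P)
}
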