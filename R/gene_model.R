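#' Posterior over candidate branching times
#'
#' Normalises per-candidate log evidences into a posterior over the candidate
#' grid (equal prior over candidates), computed with max-subtraction for
#' numerical stability. Candidates whose evidence is \code{NA} (failed fits)
#' receive zero posterior mass.
#'
#' @param log_evidence Vector of log marginal-likelihood (bound) values, one
#'   per candidate.
#' @return A probability vector summing to 1.
#' @export
branching_posterior <- function(log_evidence) {
  le <- as.numeric(log_evidence)
  le[is.na(le)] <- -Inf
  if (all(!is.finite(le))) stop("all candidate evidences are -Inf or NA")
  mx <- max(le)
  w <- exp(le - mx)
  w / sum(w)
}

#' Log Bayes factor of branching versus not branching
#'
#' \eqn{r_g = \log[\frac{1}{N_b}\sum_i p(Y|t_b = i)] - \log p(Y|t_b \to \infty)},
#' i.e. the branching evidence averaged over the candidate grid against the
#' non-branching model, assuming equal prior odds. Computed by log-sum-exp;
#' shifting all log evidences by a constant leaves \eqn{r_g} unchanged.
#'
#' @param log_evidence Per-candidate log evidences (NAs are dropped from both
#'   the sum and the count).
#' @param log_evidence_no_branch Log evidence of the non-branching model.
#' @return The scalar log Bayes factor.
#' @export
bayes_factor <- function(log_evidence, log_evidence_no_branch) {
  le <- as.numeric(log_evidence)
  le <- le[!is.na(le)]
  if (!length(le)) stop("no finite candidate evidences")
  if (!is.finite(log_evidence_no_branch)) {
    stop("'log_evidence_no_branch' must be finite")
  }
  mx <- max(le)
  (mx + log(mean(exp(le - mx)))) - log_evidence_no_branch
}

#' Smallest contiguous credible interval on the candidate grid
#'
#' Finds the shortest contiguous window of grid candidates whose posterior
#' mass reaches \code{level}; ties are broken toward earlier times.
#'
#' @param posterior Probability vector over the grid.
#' @param times Candidate times (same length); defaults to indices.
#' @param level Target mass in (0, 1).
#' @return Numeric vector \code{c(lo, hi)} in the units of \code{times}.
#' @export
credible_interval <- function(posterior, times = seq_along(posterior),
                              level = 0.98) {
  if (level <= 0 || level >= 1) stop("'level' must lie in (0, 1)")
  nb <- length(posterior)
  if (length(times) != nb) stop("posterior and times differ in length")
  cs <- c(0, cumsum(posterior))
  for (w in seq_len(nb)) {
    for (s in seq_len(nb - w + 1L)) {
      if (cs[s + w] - cs[s] >= level - 1e-12) {
        return(c(lo = times[s], hi = times[s + w - 1L]))
      }
    }
  }
  c(lo = times[1], hi = times[nb])
}

#' Fit the branching model to one gene
#'
#' Evaluates the collapsed bound on a grid of candidate branching times
#' (equally spaced over the central 90% of the pseudotime range by default),
#' warm-starting hyperparameters along the grid, fits the non-branching
#' single-GP model, and assembles the branching-time posterior, log Bayes
#' factor, MAP time, credible interval and the assignment posterior at the
#' MAP candidate. Pseudotime is rescaled to [0, 1] internally; all reported
#' times are on the original scale. Expression is centred before fitting
#' (the latent functions are zero-mean GPs).
#'
#' @param y Expression vector (one gene, length N, assumed log-scale with
#'   approximately Gaussian noise).
#' @param global A \code{\link{global_branching}} for the same cells.
#' @param config A \code{\link{bgp_config}}.
#' @param gene_id Identifier stored in the result.
#' @param grid_times Optional explicit candidate times (original scale);
#'   overrides \code{config$n_candidates}.
#' @return An object of class \code{bgp_fit}.
#' @export
fit_gene <- function(y, global, config = bgp_config(), gene_id = "gene",
                     grid_times = NULL) {
  stopifnot(inherits(global, "global_branching"))
  n <- length(y)
  if (length(global) != n) stop("y and global branching differ in length")
  rs <- rescale_global(global)
  gs <- rs$global
  ts <- gs$pseudotime
  if (is.null(grid_times)) {
    grid_s <- seq(0.05, 0.95, length.out = config$n_candidates)
  } else {
    grid_s <- sort((grid_times - rs$offset) / rs$scale)
    if (any(grid_s <= 0) || any(grid_s >= 1)) {
      stop("candidate times must lie strictly inside the pseudotime range")
    }
  }
  inducing <- choose_inducing(ts, config)
  nb <- length(grid_s)
  log_ev <- rep(NA_real_, nb)
  fits <- vector("list", nb)
  init <- NULL
  for (i in seq_len(nb)) {
    fit <- tryCatch(
      fit_branch_model(y, ts, gs, grid_s[i], config, init = init,
                       inducing_times = inducing),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      log_ev[i] <- fit$bound
      init <- list(signal_variance = fit$kernel$signal_variance,
                   lengthscale = fit$kernel$lengthscale,
                   noise_var = fit$noise_var)
    }
    fits[[i]] <- fit
  }
  n_failed <- sum(is.na(log_ev))
  if (n_failed == nb) stop("all candidate fits failed for gene ", gene_id)
  fit0 <- fit_branch_model(y, ts, gs, Inf, config, inducing_times = inducing)
  posterior <- branching_posterior(log_ev)
  rg <- bayes_factor(log_ev, fit0$bound)
  map_i <- which.max(posterior)
  ci_s <- credible_interval(posterior, grid_s, config$credible_level)
  back <- function(t) rs$offset + t * rs$scale
  structure(
    list(gene_id = gene_id,
         times = back(grid_s),
         log_evidence = log_ev,
         log_evidence_no_branch = fit0$bound,
         posterior = posterior,
         map_time = back(grid_s[map_i]),
         credible_interval = c(lo = unname(back(ci_s["lo"])),
                               hi = unname(back(ci_s["hi"]))),
         bayes_factor = rg,
         credible_level = config$credible_level,
         phi_map = fits[[map_i]]$phi,
         kernel_map = fits[[map_i]]$kernel,
         noise_var_map = fits[[map_i]]$noise_var,
         kernel_no_branch = fit0$kernel,
         noise_var_no_branch = fit0$noise_var,
         n_failed = n_failed,
         flagged = n_failed > nb / 2,
         converged = vapply(fits, function(f) isTRUE(f$converged), TRUE),
         center = mean(y),
         time_offset = rs$offset, time_scale = rs$scale,
         inducing_times = inducing,
         n = n),
    class = "bgp_fit"
  )
}

#' @export
print.bgp_fit <- function(x, ...) {
  cat(sprintf(
    paste0("BGP fit for %s (N = %d): log BF = %.2f, MAP branching time = %.4g,",
           " %d%% CI [%.4g, %.4g]%s\n"),
    x$gene_id, x$n, x$bayes_factor, x$map_time,
    round(100 * (x$credible_level %||% 0.98)),
    x$credible_interval["lo"], x$credible_interval["hi"],
    if (x$flagged) " [flagged: >50% candidate fits failed]" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the branching model to many genes
#'
#' Applies \code{\link{fit_gene}} to every row of an expression matrix.
#' Genes are independent work units; results do not depend on the order in
#' which they are fitted. Per-gene failures are collected rather than
#' aborting the run.
#'
#' @param expr Genes x cells numeric matrix (row names = gene ids, column
#'   order matching \code{global}).
#' @param global A \code{\link{global_branching}}.
#' @param config A \code{\link{bgp_config}}.
#' @param genes Optional subset of gene ids (default: all rows).
#' @param verbose Print one progress line per gene.
#' @return An object of class \code{bgp_fits}: a named list of
#'   \code{bgp_fit} objects (failed genes are dropped with a warning).
#' @export
fit_genes <- function(expr, global, config = bgp_config(), genes = NULL,
                      verbose = FALSE) {
  expr <- check_expression(expr)
  if (!is.null(global$cell_id) && !is.null(colnames(expr))) {
    missing <- setdiff(colnames(expr), global$cell_id)
    if (length(missing)) {
      stop("cells present in expression but absent from the global ",
           "branching: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    global <- subset_global(global, match(colnames(expr), global$cell_id))
  }
  if (ncol(expr) != length(global)) {
    stop("expression columns and global branching cells differ in number")
  }
  if (is.null(genes)) genes <- rownames(expr)
  fits <- list()
  for (g in genes) {
    t0 <- proc.time()[3]
    fit <- tryCatch(fit_gene(expr[g, ], global, config, gene_id = g),
                    error = function(e) {
                      warning("gene ", g, " failed: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(fit)) fits[[g]] <- fit
    if (verbose && !is.null(fit)) {
      message(sprintf("%s: log BF %.1f, MAP %.3f (%.1fs)", g,
                      fit$bayes_factor, fit$map_time, proc.time()[3] - t0))
    }
  }
  structure(fits, class = "bgp_fits")
}

#' Summarise per-gene branching fits
#'
#' @param object A \code{bgp_fits} collection.
#' @param ... Unused.
#' @return A data frame with one row per gene: \code{gene_id},
#'   \code{map_time}, \code{ci_lo}, \code{ci_hi}, \code{bayes_factor},
#'   \code{n_candidates_failed}.
#' @export
summary.bgp_fits <- function(object, ...) {
  do.call(rbind, lapply(unname(object), function(f) {
    data.frame(gene_id = f$gene_id, map_time = f$map_time,
               ci_lo = f$credible_interval["lo"],
               ci_hi = f$credible_interval["hi"],
               bayes_factor = f$bayes_factor,
               n_candidates_failed = f$n_failed,
               row.names = NULL)
  }))
}

#' @export
print.bgp_fits <- function(x, ...) {
  cat(sprintf("BGP fits for %d genes\n", length(x)))
  print(utils::head(summary(x), 10))
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

#' Predictive branch curves at the MAP candidate
#'
#' Gaussian predictive mean and variance of the trunk and both branch latent
#' functions at query pseudotimes, under the MAP-candidate model and the
#' fitted assignment posterior (which weights each observation's
#' contribution to each latent function). At the MAP branching time the
#' three predictive means coincide by the kernel constraint; far from the
#' data the prediction reverts to the zero-mean prior with the signal
#' variance.
#'
#' @param fit A \code{\link{fit_gene}} result.
#' @param y,global The data the gene was fitted on.
#' @param t_query Query pseudotimes (original scale).
#' @return A data frame with columns \code{t}, \code{branch}
#'   (\code{"trunk"}, \code{"1"}, \code{"2"}), \code{mean}, \code{var}
#'   (latent-function variance, excluding observation noise). The centring
#'   constant removed before fitting is added back to the means.
#' @export
predict_branches <- function(fit, y, global, t_query) {
  stopifnot(inherits(fit, "bgp_fit"))
  ts <- (global$pseudotime - fit$time_offset) / fit$time_scale
  tq <- (t_query - fit$time_offset) / fit$time_scale
  yc <- y - fit$center
  kern <- fit$kernel_map
  s2 <- fit$noise_var_map
  phi <- fit$phi_map
  jit <- 1e-6
  a <- as.vector(phi)
  r <- as.vector(phi * yc)
  xq <- aug_full(tq)
  x <- aug_full(ts)
  if (is.null(fit$inducing_times)) {
    # q(F) is GP regression on pseudo-data r/a with noise s2/a (a > 0)
    keep <- a > 1e-10
    Kxx <- branching_cov(kern, x$t[keep], x$f[keep])
    diag(Kxx) <- diag(Kxx) + s2 / a[keep] + jit * kern$signal_variance
    Kqx <- branching_cov(kern, xq$t, xq$f, x$t[keep], x$f[keep])
    U <- chol(Kxx)
    alpha <- backsolve(U, forwardsolve(t(U), r[keep] / a[keep]))
    mean_q <- as.vector(Kqx %*% alpha)
    W <- forwardsolve(t(U), t(Kqx))
    var_q <- pmax(kern$signal_variance - colSums(W^2), 0)
  } else {
    u <- aug_full(fit$inducing_times)
    Kuu <- branching_cov(kern, u$t, u$f)
    diag(Kuu) <- diag(Kuu) + jit * kern$signal_variance
    Kux <- branching_cov(kern, u$t, u$f, x$t, x$f)
    Kuq <- branching_cov(kern, u$t, u$f, xq$t, xq$f)
    Ka <- Kux * rep(a, each = nrow(Kux))
    Lam <- tcrossprod(Ka, Kux) / s2 + Kuu
    cholL <- chol(Lam)
    Hq <- forwardsolve(t(cholL), Kuq)
    Hx <- forwardsolve(t(cholL), Kux)
    mean_q <- as.vector(crossprod(Hq, Hx %*% r)) / s2
    Lu <- chol(Kuu)
    Vq <- forwardsolve(t(Lu), Kuq)
    var_q <- pmax(kern$signal_variance - colSums(Vq^2), 0) + colSums(Hq^2)
  }
  data.frame(t = rep(t_query, 3),
             branch = rep(c("trunk", "1", "2"), each = length(t_query)),
             mean = mean_q + fit$center,
             var = var_q)
}

#' Welch t-statistic prefilter on branch end states
#'
#' For each gene, compares expression over the latest \code{tail_fraction}
#' of cells (by pseudotime, within each branch) between the two branches
#' with a Welch two-sample t-statistic, and keeps genes with
#' \code{|t| >= threshold}. Used to shortlist plausibly branching genes
#' before the expensive per-gene model fits.
#'
#' @param expr Genes x cells matrix.
#' @param global A \code{\link{global_branching}}.
#' @param tail_fraction Fraction of each branch's cells forming the end
#'   state window (latest pseudotimes).
#' @param threshold Absolute t-statistic cut-off.
#' @return A list with \code{keep} (gene ids passing the filter) and
#'   \code{stats} (data frame: gene_id, t_stat, n1, n2).
#' @export
t_filter <- function(expr, global, tail_fraction = 0.25, threshold = 2) {
  expr <- check_expression(expr)
  if (ncol(expr) != length(global)) {
    stop("expression columns and global branching cells differ in number")
  }
  if (tail_fraction <= 0 || tail_fraction > 1) {
    stop("'tail_fraction' must lie in (0, 1]")
  }
  tail_idx <- function(branch) {
    i <- which(global$label == branch)
    if (!length(i)) return(integer(0))
    k <- max(ceiling(tail_fraction * length(i)), 1L)
    i[order(global$pseudotime[i], decreasing = TRUE)][seq_len(k)]
  }
  i1 <- tail_idx("1")
  i2 <- tail_idx("2")
  if (length(i1) < 3 || length(i2) < 3) {
    stop("each branch needs at least 3 cells in its end-state window")
  }
  tstat <- vapply(rownames(expr), function(g) {
    tryCatch(unname(stats::t.test(expr[g, i1], expr[g, i2])$statistic),
             error = function(e) {
               warning("gene ", g, " skipped in t_filter: ",
                       conditionMessage(e))
               NA_real_
             })
  }, numeric(1))
  stats_df <- data.frame(gene_id = rownames(expr), t_stat = tstat,
                         n1 = length(i1), n2 = length(i2),
                         row.names = NULL)
  list(keep = stats_df$gene_id[!is.na(tstat) & abs(tstat) >= threshold],
       stats = stats_df)
}

# Validate an expression matrix: numeric, finite, unique dimnames.
check_expression <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr)) expr <- matrix(expr, nrow = 1)
  if (!is.numeric(expr)) stop("expression matrix must be numeric")
  if (any(!is.finite(expr))) stop("expression matrix contains non-finite values")
  if (is.null(rownames(expr))) {
    rownames(expr) <- paste0("gene_", seq_len(nrow(expr)))
  }
  dup <- rownames(expr)[duplicated(rownames(expr))]
  if (length(dup)) stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  if (!is.null(colnames(expr))) {
    dupc <- colnames(expr)[duplicated(colnames(expr))]
    if (length(dupc)) {
      stop("duplicate cell ids: ", paste(unique(dupc), collapse = ", "))
    }
  }
  expr
}
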