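#' Synthetic study configuration
#'
#' Describes a synthetic branching-expression dataset with known ground
#' truth. The defaults reproduce the standard simulation design: N = 150
#' cells on a unit pseudotime interval, 40 genes in three groups (10
#' branching early at 0.2, 20 late at 0.8, 10 not branching), branching-GP
#' draws with signal variance 2 and lengthscale 1.2, and additive Gaussian
#' observation noise.
#'
#' @param n_cells Number of cells N.
#' @param gene_groups Data frame with columns \code{branch_time} (NA for
#'   non-branching) and \code{n_genes}.
#' @param signal_variance,lengthscale Base-kernel hyperparameters of the
#'   generating branching GP.
#' @param noise_variance Observation noise variance.
#' @param prior_confidence Prior assignment confidence intended for fitting
#'   this dataset (echoed into provenance; 0.8 is the informative-prior
#'   setting of the benchmark).
#' @param seed RNG seed (R's default Mersenne-Twister generator; the same
#'   seed reproduces the dataset exactly).
#' @return An object of class \code{bgp_synth_config}.
#' @export
synthetic_config <- function(n_cells = 150,
                             gene_groups = data.frame(
                               branch_time = c(0.2, 0.8, NA),
                               n_genes = c(10L, 20L, 10L)),
                             signal_variance = 2, lengthscale = 1.2,
                             noise_variance = 0.001,
                             prior_confidence = 0.8, seed = 1) {
  stopifnot(is.data.frame(gene_groups),
            all(c("branch_time", "n_genes") %in% names(gene_groups)))
  if (any(gene_groups$n_genes < 0)) stop("gene counts must be non-negative")
  bt <- gene_groups$branch_time
  if (any(!is.na(bt) & (bt <= 0 | bt >= 1))) {
    stop("branching times must lie in (0, 1)")
  }
  if (noise_variance <= 0) stop("'noise_variance' must be positive")
  structure(
    list(n_cells = as.integer(n_cells), gene_groups = gene_groups,
         signal_variance = signal_variance, lengthscale = lengthscale,
         noise_variance = noise_variance,
         prior_confidence = prior_confidence, seed = as.integer(seed)),
    class = "bgp_synth_config"
  )
}

#' Draw one branching gene from the generative model
#'
#' Samples the three latent functions jointly from the constrained branching
#' prior at the given pseudotimes, assigns each post-branch cell to its
#' branch, and adds iid Gaussian noise. Draws in which the two branch
#' functions cross again after the branching point (a sign change of
#' \eqn{g - h} between consecutive post-branch evaluation points) are
#' rejected and redrawn, since such trajectories are ambiguous for any
#' branching-time estimator; at most \code{max_reject} redraws are
#' attempted. Pre-branch behaviour is unaffected by this filter.
#'
#' @param times Pseudotimes in [0, 1].
#' @param branch_time True branching time in (0, 1).
#' @param membership Character vector ("1"/"2") giving each cell's branch
#'   (used only for cells with \code{times >= branch_time}); defaults to a
#'   fair coin per cell.
#' @param kernel A \code{\link{branching_kernel}} template (its
#'   \code{branch_point} is replaced by \code{branch_time}).
#' @param noise_variance Observation noise variance.
#' @param max_reject Rejection budget.
#' @return A list with \code{y} (expression), \code{latent} (N x 3 matrix of
#'   trunk/branch-1/branch-2 values), \code{cell_branch} (character,
#'   "trunk"/"1"/"2"), and \code{n_rejected}.
#' @export
sample_branching_gene <- function(times, branch_time, membership = NULL,
                                  kernel = branching_kernel(2, 1.2),
                                  noise_variance = 0.001,
                                  max_reject = 1000) {
  n <- length(times)
  if (branch_time <= 0 || branch_time >= 1) {
    stop("'branch_time' must lie in (0, 1)")
  }
  if (is.null(membership)) {
    membership <- sample(c("1", "2"), n, replace = TRUE)
  }
  kern <- branching_kernel(kernel$signal_variance, kernel$lengthscale,
                           branch_time)
  K <- bgp_cov_jittered(kern, times)
  U <- chol(K)
  post <- which(times >= branch_time)
  for (try in seq_len(max_reject + 1L)) {
    F3 <- matrix(as.vector(stats::rnorm(3 * n) %*% U), n, 3)
    d <- F3[post, 2] - F3[post, 3]
    crossing <- length(post) > 1 && any(d[-length(d)] * d[-1] < 0)
    if (!crossing) break
    if (try > max_reject) {
      stop("rejection budget exhausted; consider a longer lengthscale")
    }
  }
  cell_branch <- rep("trunk", n)
  cell_branch[post] <- membership[post]
  col_idx <- c(trunk = 1, "1" = 2, "2" = 3)[cell_branch]
  y <- F3[cbind(seq_len(n), col_idx)] +
    stats::rnorm(n, sd = sqrt(noise_variance))
  list(y = y, latent = F3, cell_branch = cell_branch, n_rejected = try - 1L)
}

#' Draw one non-branching gene
#'
#' A single zero-mean GP draw with the base kernel plus iid Gaussian noise;
#' no branch structure.
#'
#' @inheritParams sample_branching_gene
#' @return Numeric expression vector.
#' @export
sample_nonbranching_gene <- function(times, kernel = branching_kernel(2, 1.2),
                                     noise_variance = 0.001) {
  K <- se_cov(times, times, kernel$signal_variance, kernel$lengthscale)
  diag(K) <- diag(K) + 1e-6 * kernel$signal_variance
  as.vector(stats::rnorm(length(times)) %*% chol(K)) +
    stats::rnorm(length(times), sd = sqrt(noise_variance))
}

#' Generate a benchmark dataset with known ground truth
#'
#' Draws sorted-uniform pseudotimes on [0, 1], a dataset-level branch
#' membership (one fair coin per cell, shared by all genes so that a single
#' global branching structure is meaningful), and one expression profile per
#' gene from \code{\link{sample_branching_gene}} /
#' \code{\link{sample_nonbranching_gene}}. The oracle global branching uses
#' the true shared memberships and the earliest true branching time;
#' \code{\link{corrupt_global_labels}} can emulate imperfect upstream tools.
#' Fully reproducible from \code{config$seed}.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return An object of class \code{bgp_dataset}: list with \code{expr}
#'   (genes x cells), \code{pseudotime}, \code{true_branch_time} (named, NA
#'   for non-branching genes), \code{true_cell_branch} (genes x cells
#'   character matrix), \code{membership}, \code{global}
#'   (\code{\link{global_branching}}, source \code{"truth"}) and
#'   \code{config}.
#' @export
make_benchmark <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "bgp_synth_config"))
  set.seed(config$seed)
  n <- config$n_cells
  times <- sort(stats::runif(n))
  membership <- sample(c("1", "2"), n, replace = TRUE)
  kern <- branching_kernel(config$signal_variance, config$lengthscale)
  groups <- config$gene_groups
  bt_per_gene <- rep(groups$branch_time, groups$n_genes)
  n_genes <- length(bt_per_gene)
  gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
  expr <- matrix(NA_real_, n_genes, n,
                 dimnames = list(gene_ids, sprintf("cell_%03d", seq_len(n))))
  cell_branch <- matrix("trunk", n_genes, n, dimnames = dimnames(expr))
  for (g in seq_len(n_genes)) {
    if (is.na(bt_per_gene[g])) {
      expr[g, ] <- sample_nonbranching_gene(times, kern,
                                            config$noise_variance)
    } else {
      s <- sample_branching_gene(times, bt_per_gene[g], membership, kern,
                                 config$noise_variance)
      expr[g, ] <- s$y
      cell_branch[g, ] <- s$cell_branch
    }
  }
  finite_bt <- bt_per_gene[!is.na(bt_per_gene)]
  if (!length(finite_bt)) stop("benchmark needs at least one branching gene")
  global_bt <- min(finite_bt)
  glab <- ifelse(times < global_bt, "trunk", membership)
  global <- global_branching(times, glab, global_bt,
                             cell_id = colnames(expr), source = "truth")
  structure(
    list(expr = expr, pseudotime = times,
         true_branch_time = stats::setNames(bt_per_gene, gene_ids),
         true_cell_branch = cell_branch, membership = membership,
         global = global, config = config),
    class = "bgp_dataset"
  )
}

#' @export
print.bgp_dataset <- function(x, ...) {
  nb <- sum(!is.na(x$true_branch_time))
  cat(sprintf(
    "Synthetic branching dataset: %d genes (%d branching) x %d cells, noise %.4g, seed %d\n",
    nrow(x$expr), nb, ncol(x$expr), x$config$noise_variance, x$config$seed))
  invisible(x)
}

#' Corrupt global branch labels
#'
#' Independently flips post-branch labels ("1" <-> "2") with probability
#' \code{flip_rate}, emulating errors in the upstream global branching
#' assignment. \code{flip_rate = 0.5} destroys all label information.
#'
#' @param global A \code{\link{global_branching}}.
#' @param flip_rate Flip probability in [0, 0.5].
#' @param seed Optional seed.
#' @return A new \code{global_branching} (source suffixed with
#'   \code{"+flipped"}).
#' @export
corrupt_global_labels <- function(global, flip_rate, seed = NULL) {
  if (flip_rate < 0 || flip_rate > 0.5) {
    stop("'flip_rate' must lie in [0, 0.5]")
  }
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(global$label)
  post <- which(lab != "trunk")
  flip <- post[stats::runif(length(post)) < flip_rate]
  lab[flip] <- ifelse(lab[flip] == "1", "2", "1")
  global_branching(global$pseudotime, lab, global$branch_time,
                   cell_id = global$cell_id,
                   source = paste0(global$source, "+flipped"))
}

#' Balanced subsampling across trunk and branches
#'
#' Stratified sampling of cells toward equal counts per stratum (trunk,
#' branch 1, branch 2). A stratum smaller than its quota is kept in full and
#' the remainder of the target is redistributed among the other strata.
#' Deterministic given \code{seed}.
#'
#' @param expr Genes x cells matrix.
#' @param global A \code{\link{global_branching}} for the same cells.
#' @param n_target Total number of cells to keep (at most N).
#' @param seed Optional seed.
#' @return A list with the subsampled \code{expr} and \code{global}.
#' @export
balanced_subsample <- function(expr, global, n_target, seed = NULL) {
  expr <- check_expression(expr)
  if (ncol(expr) != length(global)) {
    stop("expression columns and global branching cells differ in number")
  }
  if (n_target > length(global)) stop("'n_target' exceeds the cell count")
  if (!is.null(seed)) set.seed(seed)
  lab <- as.character(global$label)
  strata <- split(seq_along(lab), factor(lab, levels = c("trunk", "1", "2")))
  sizes <- lengths(strata)
  quota <- stats::setNames(integer(3), names(strata))
  remaining <- as.integer(n_target)
  open <- sizes > 0
  while (remaining > 0 && any(open & quota < sizes)) {
    can_grow <- which(open & quota < sizes)
    share <- floor(remaining / length(can_grow))
    if (share == 0) {
      # hand out the last few cells one by one, smallest quota first
      ord <- can_grow[order(quota[can_grow])]
      take <- ord[seq_len(min(remaining, length(ord)))]
      quota[take] <- quota[take] + 1L
      remaining <- remaining - length(take)
    } else {
      add <- pmin(share, sizes[can_grow] - quota[can_grow])
      quota[can_grow] <- quota[can_grow] + add
      remaining <- remaining - sum(add)
    }
  }
  idx <- sort(unlist(mapply(function(cells, k) {
    if (k >= length(cells)) cells else sample(cells, k)
  }, strata, quota, SIMPLIFY = FALSE), use.names = FALSE))
  list(expr = expr[, idx, drop = FALSE], global = subset_global(global, idx))
}
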