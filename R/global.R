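#' Global branching structure
#'
#' Container for the dataset-wide branching information estimated upstream
#' (e.g. by Monocle-DDRTree, DPT or Wishbone): per-cell pseudotime, per-cell
#' global branch labels and the global branching time. The branching model
#' uses this only to build the assignment prior; pseudotime and gene-wise
#' branch structure are then inferred per gene.
#'
#' Labels use the fixed vocabulary \code{"trunk"}, \code{"1"}, \code{"2"}.
#' Mapping labels produced by upstream tools onto this vocabulary is the
#' caller's responsibility. Trunk labels occurring at or after the global
#' branching time are permitted but trigger a warning; such cells receive an
#' uninformative branch prior during fitting.
#'
#' @param pseudotime Numeric vector, one value per cell.
#' @param label Character/factor vector over \code{c("trunk", "1", "2")}.
#' @param branch_time Global branching time, on the same scale as
#'   \code{pseudotime}.
#' @param cell_id Optional cell identifiers (defaults to \code{cell_1}, ...).
#' @param source Free-text provenance, e.g. \code{"DPT"} or \code{"truth"}.
#' @return An object of class \code{global_branching}.
#' @export
global_branching <- function(pseudotime, label, branch_time,
                             cell_id = NULL, source = "user") {
  pseudotime <- as.numeric(pseudotime)
  if (anyNA(pseudotime) || any(!is.finite(pseudotime))) {
    stop("pseudotime must be finite")
  }
  lab <- as.character(label)
  bad <- setdiff(unique(lab), c("trunk", "1", "2"))
  if (length(bad)) {
    stop("unknown branch labels: ", paste(bad, collapse = ", "),
         " (expected 'trunk', '1', '2')")
  }
  if (length(lab) != length(pseudotime)) {
    stop("pseudotime and label differ in length")
  }
  if (!is.numeric(branch_time) || length(branch_time) != 1L ||
      !is.finite(branch_time)) {
    stop("'branch_time' must be a single finite number")
  }
  if (is.null(cell_id)) cell_id <- paste0("cell_", seq_along(pseudotime))
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("duplicate cell ids")
  if (any(lab == "trunk" & pseudotime >= branch_time)) {
    warning("trunk labels at or after the global branching time; ",
            "these cells get an uninformative branch prior")
  }
  structure(
    list(cell_id = cell_id, pseudotime = pseudotime,
         label = factor(lab, levels = c("trunk", "1", "2")),
         branch_time = branch_time, source = as.character(source)[1]),
    class = "global_branching"
  )
}

#' @export
print.global_branching <- function(x, ...) {
  cat(sprintf(
    "Global branching (%s): %d cells, branching time %.4g, labels trunk/1/2 = %d/%d/%d\n",
    x$source, length(x$pseudotime), x$branch_time,
    sum(x$label == "trunk"), sum(x$label == "1"), sum(x$label == "2")))
  invisible(x)
}

#' @export
length.global_branching <- function(x) length(x$pseudotime)

# Subset cells of a global_branching (used by the balanced subsampler).
subset_global <- function(global, idx) {
  global_branching(global$pseudotime[idx], as.character(global$label)[idx],
                   global$branch_time, cell_id = global$cell_id[idx],
                   source = global$source)
}

# Min-max rescale pseudotime (and the branching time) to [0, 1]; returns the
# rescaled object plus the affine map needed to report results on the
# original scale.
rescale_global <- function(global) {
  lo <- min(global$pseudotime)
  rng <- diff(range(global$pseudotime))
  if (rng <= 0) stop("pseudotime has zero range")
  g <- global
  g$pseudotime <- (global$pseudotime - lo) / rng
  g$branch_time <- (global$branch_time - lo) / rng
  list(global = g, offset = lo, scale = rng)
}
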