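#' Read a gene x cell expression matrix
#'
#' Supports two plain-text formats: CSV with genes as rows (first column =
#' gene ids, header = cell ids) and MatrixMarket MTX with \code{genes.tsv} /
#' \code{barcodes.tsv} sidecars (first column of each sidecar is used).
#' Values must be numeric and finite (the model assumes log-transformed,
#' normalised expression); duplicate gene or cell ids are an error.
#'
#' @param path Path to the \code{.csv} or \code{.mtx} file.
#' @param genes_path,cells_path Sidecar paths for MTX input; default to
#'   \code{genes.tsv} and \code{barcodes.tsv} next to the matrix.
#' @return A dense numeric matrix with gene row names and cell column names.
#' @export
read_expression <- function(path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(cells_path)) {
      cells_path <- file.path(dirname(path), "barcodes.tsv")
    }
    genes <- utils::read.delim(genes_path, header = FALSE,
                               comment.char = "#")[[1]]
    cells <- utils::read.delim(cells_path, header = FALSE,
                               comment.char = "#")[[1]]
    if (length(genes) != nrow(m)) {
      stop(sprintf("gene sidecar has %d entries but the matrix has %d rows",
                   length(genes), nrow(m)))
    }
    if (length(cells) != ncol(m)) {
      stop(sprintf(
        "barcode sidecar has %d entries but the matrix has %d columns",
        length(cells), ncol(m)))
    }
    dimnames(m) <- list(as.character(genes), as.character(cells))
  } else {
    df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) stop("duplicate gene ids: ", paste(dup, collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(apply(df[, -1, drop = FALSE], 2,
                         function(col) any(is.na(suppressWarnings(
                           as.numeric(col))) & !is.na(col))))
      stop("non-numeric expression values in column(s): ",
           paste(names(bad), collapse = ", "))
    }
    rownames(m) <- ids
  }
  check_expression(m)
}

#' Write an expression matrix as CSV
#'
#' Genes as rows, cells as columns; an optional provenance header is written
#' as leading comment lines that \code{\link{read_expression}} skips.
#'
#' @param expr Genes x cells matrix.
#' @param path Output path.
#' @param provenance Optional named list echoed as header comments.
#' @return Invisibly, \code{expr}.
#' @export
write_expression <- function(expr, path, provenance = NULL) {
  expr <- check_expression(expr)
  con <- file(path, "w")
  writeLines(provenance_header(provenance), con)
  utils::write.csv(data.frame(gene_id = rownames(expr), expr,
                              check.names = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(expr)
}

#' Read a global branching table
#'
#' TSV with columns \code{cell_id}, \code{pseudotime}, \code{branch} (values
#' \code{trunk}, \code{1}, \code{2}). The global branching time is read from
#' a \code{# global_branch_time=<x>} header comment unless supplied
#' explicitly. Pseudotime can optionally be min-max rescaled to [0, 1]
#' (recorded in the returned object's \code{source}).
#'
#' @param path Path to the TSV file.
#' @param branch_time Global branching time; overrides the header comment.
#' @param rescale Rescale pseudotime (and the branching time) to [0, 1].
#' @param source Provenance string.
#' @return A \code{\link{global_branching}}.
#' @export
read_global_branching <- function(path, branch_time = NULL, rescale = FALSE,
                                  source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- grep("^#", readLines(path, n = 20), value = TRUE)
  if (is.null(branch_time)) {
    bt_line <- grep("global_branch_time=", head_lines, value = TRUE)
    if (length(bt_line)) {
      branch_time <- as.numeric(sub(".*global_branch_time=", "", bt_line[1]))
    } else {
      stop("no global branching time: pass 'branch_time' or add a ",
           "'# global_branch_time=<x>' header")
    }
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(branch = "character"))
  need <- c("cell_id", "pseudotime", "branch")
  if (!all(need %in% names(df))) {
    stop("missing column(s): ", paste(setdiff(need, names(df)),
                                      collapse = ", "))
  }
  g <- global_branching(df$pseudotime, df$branch, branch_time,
                        cell_id = df$cell_id, source = source)
  if (rescale) {
    rs <- rescale_global(g)
    g <- rs$global
    g$source <- paste0(g$source, " (rescaled to [0,1])")
  }
  g
}

#' Write a global branching table
#'
#' @param global A \code{\link{global_branching}}.
#' @param path Output TSV path.
#' @param provenance Optional named list echoed as header comments.
#' @return Invisibly, \code{global}.
#' @export
write_global_branching <- function(global, path, provenance = NULL) {
  con <- file(path, "w")
  writeLines(c(provenance_header(provenance),
               sprintf("# global_branch_time=%.17g", global$branch_time)),
             con)
  utils::write.table(
    data.frame(cell_id = global$cell_id, pseudotime = global$pseudotime,
               branch = as.character(global$label)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(global)
}

#' Write a synthetic dataset to a directory
#'
#' Writes \code{expression.csv}, \code{global.tsv} and a ground-truth
#' \code{truth.json} (per-gene true branching times, per-cell memberships,
#' seed and config echo) so a benchmark dataset round-trips losslessly.
#'
#' @param dataset A \code{\link{make_benchmark}} result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "bgp_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "branchgp",
               version = as.character(utils::packageVersion("branchgp")),
               seed = dataset$config$seed)
  write_expression(dataset$expr, file.path(dir, "expression.csv"), prov)
  write_global_branching(dataset$global, file.path(dir, "global.tsv"), prov)
  cfg <- dataset$config
  truth <- list(
    true_branch_time = as.list(dataset$true_branch_time),
    membership = dataset$membership,
    pseudotime = dataset$pseudotime,
    config = list(n_cells = cfg$n_cells,
                  gene_groups = cfg$gene_groups,
                  signal_variance = cfg$signal_variance,
                  lengthscale = cfg$lengthscale,
                  noise_variance = cfg$noise_variance,
                  prior_confidence = cfg$prior_confidence,
                  seed = cfg$seed),
    provenance = prov)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a synthetic dataset directory
#'
#' @param dir Directory written by \code{\link{write_dataset}}.
#' @return A list with \code{expr}, \code{global} and \code{truth} (the
#'   parsed ground-truth record).
#' @export
read_dataset <- function(dir) {
  expr <- read_expression(file.path(dir, "expression.csv"))
  global <- read_global_branching(file.path(dir, "global.tsv"),
                                  source = "truth")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(expr = expr, global = global, truth = truth)
}

#' Write per-gene fit results to a directory store
#'
#' Writes the summary table as \code{results.tsv} plus, per gene, the
#' posterior over the candidate grid and the assignment posterior at the
#' MAP candidate as CSV files under \code{posteriors/} and \code{phi/}.
#'
#' @param fits A \code{bgp_fits} collection.
#' @param dir Output directory.
#' @param provenance Optional named list echoed as header comments.
#' @return Invisibly, the directory path.
#' @export
write_fits <- function(fits, dir, provenance = NULL) {
  dir.create(file.path(dir, "posteriors"), showWarnings = FALSE,
             recursive = TRUE)
  dir.create(file.path(dir, "phi"), showWarnings = FALSE)
  con <- file(file.path(dir, "results.tsv"), "w")
  writeLines(provenance_header(provenance), con)
  utils::write.table(summary(fits), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  for (f in fits) {
    utils::write.csv(
      data.frame(time = f$times, log_evidence = f$log_evidence,
                 posterior = f$posterior),
      file.path(dir, "posteriors", paste0(f$gene_id, ".csv")),
      row.names = FALSE)
    utils::write.csv(
      data.frame(trunk = f$phi_map[, 1], branch1 = f$phi_map[, 2],
                 branch2 = f$phi_map[, 3]),
      file.path(dir, "phi", paste0(f$gene_id, ".csv")),
      row.names = FALSE)
  }
  invisible(dir)
}

# "# key=value" provenance comment lines (package version always included).
provenance_header <- function(provenance = NULL) {
  prov <- c(list(package = "branchgp"), provenance)
  vapply(names(prov), function(k) {
    sprintf("# %s=%s", k, paste(format(prov[[k]]), collapse = ","))
  }, "")
}
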