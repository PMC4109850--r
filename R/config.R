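#' Analysis configuration
#'
#' Bundles the tunable parameters shared across the fitting, network
#' extraction, preprocessing and downstream stages. Defaults follow the
#' published analysis protocol for the breast-cell panel: the regularization
#' grids are the values explored for the real data, the 1.3 fold-change
#' cut-off defines the gene-variability filter, hubs are genes of positive
#' degree strictly greater than 5, displayed edges have absolute weight above
#' 0.1, and enrichment FDR cut-offs are 0.1 (pathways, hypergeometric) and
#' 0.05 (GO, Fisher).
#'
#' @param lambda1 sparsity penalty weight (nonnegative).
#' @param lambda2 total-variation fusion penalty weight (nonnegative).
#' @param lambda1_grid grid of candidate `lambda1` values.
#' @param lambda2_grid grid of candidate `lambda2` values.
#' @param zero_tol coefficients with absolute value at or below this threshold
#'   are stored as exact zeros (support extraction).
#' @param solver_tol target absolute accuracy of the solver objective.
#' @param seed integer seed used when randomness is involved.
#' @param fc_threshold fold-change filter threshold (> 1, linear scale).
#' @param hub_degree hub definition: degree strictly greater than this.
#' @param edge_display_threshold absolute-weight display cut-off.
#' @param fdr_pathway BH FDR cut-off for pathway enrichment.
#' @param fdr_go BH FDR cut-off for GO enrichment.
#' @return an object of class `analysis_config` (a validated list).
#' @examples
#' cfg <- analysis_config(lambda1 = 5, lambda2 = 1)
#' cfg$lambda1_grid
#' @export
analysis_config <- function(lambda1 = 5,
                            lambda2 = 1,
                            lambda1_grid = c(4, 4.5, 5, 5.5, 6, 6.5, 7),
                            lambda2_grid = c(0.5, 1, 1.5, 2, 2.5),
                            zero_tol = 1e-6,
                            solver_tol = 1e-6,
                            seed = 1L,
                            fc_threshold = 1.3,
                            hub_degree = 5L,
                            edge_display_threshold = 0.1,
                            fdr_pathway = 0.1,
                            fdr_go = 0.05) {
  stopifnot(
    is.numeric(lambda1), length(lambda1) == 1L, lambda1 >= 0,
    is.numeric(lambda2), length(lambda2) == 1L, lambda2 >= 0,
    is.numeric(lambda1_grid), all(lambda1_grid >= 0),
    is.numeric(lambda2_grid), all(lambda2_grid >= 0),
    is.numeric(zero_tol), zero_tol > 0,
    is.numeric(solver_tol), solver_tol > 0,
    is.numeric(seed), length(seed) == 1L
  )
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    stop("`fc_threshold` must be a real > 1")
  }
  if (!is.numeric(hub_degree) || hub_degree < 1) {
    stop("`hub_degree` must be a positive integer")
  }
  if (edge_display_threshold < 0) {
    stop("`edge_display_threshold` must be nonnegative")
  }
  for (f in c(fdr_pathway, fdr_go)) {
    if (!is.numeric(f) || f <= 0 || f >= 1) {
      stop("FDR cut-offs must lie in (0, 1)")
    }
  }
  structure(
    list(
      lambda1 = as.numeric(lambda1),
      lambda2 = as.numeric(lambda2),
      lambda1_grid = as.numeric(lambda1_grid),
      lambda2_grid = as.numeric(lambda2_grid),
      zero_tol = as.numeric(zero_tol),
      solver_tol = as.numeric(solver_tol),
      seed = as.integer(seed),
      fc_threshold = as.numeric(fc_threshold),
      hub_degree = as.integer(hub_degree),
      edge_display_threshold = as.numeric(edge_display_threshold),
      fdr_pathway = as.numeric(fdr_pathway),
      fdr_go = as.numeric(fdr_go)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  lambda1 =", x$lambda1, " lambda2 =", x$lambda2, "\n")
  cat("  lambda1_grid:", paste(x$lambda1_grid, collapse = ", "), "\n")
  cat("  lambda2_grid:", paste(x$lambda2_grid, collapse = ", "), "\n")
  cat("  zero_tol =", x$zero_tol, " solver_tol =", x$solver_tol, "\n")
  cat("  fc_threshold =", x$fc_threshold, " hub_degree >", x$hub_degree, "\n")
  invisible(x)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key=value`; values that parse as numeric vectors
#' (comma-separated) are converted. Unknown keys are rejected.
#'
#' @param path path to the configuration file.
#' @return an [analysis_config()] object.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(analysis_config))) {
      stop("unknown config key: ", key)
    }
    num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
    args[[key]] <- if (anyNA(num)) val else num
  }
  do.call(analysis_config, args)
}
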