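#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#' `seed = NULL` evaluates the code against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed from a master seed; stays within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#' @param level one of "debug", "info", "warn", "error".
#' @return the previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("treeglasso.log_level", "info")
  options(treeglasso.log_level = level)
  invisible(old)
}

log_msg <- function(level, ...) {
  cur <- getOption("treeglasso.log_level", "info")
  if (.log_levels[[level]] >= .log_levels[[cur]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

# canonical (lexicographic) unordered pair keys for edge bookkeeping;
# gene ids come from TSV columns, so a tab cannot occur inside an id
edge_keys <- function(gene_i, gene_j) {
  swap <- gene_i > gene_j
  a <- ifelse(swap, gene_j, gene_i)
  b <- ifelse(swap, gene_i, gene_j)
  paste(a, b, sep = "\t")
}

split_edge_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(gene_i = character(), gene_j = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(gene_i = vapply(parts, `[[`, "", 1L),
             gene_j = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

soft_threshold <- function(x, thr) {
  sign(x) * pmax(abs(x) - thr, 0)
}

# full-precision numeric formatting for lossless TSV round trips
num_chr <- function(x) {
  sprintf("%.17g", x)
}
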