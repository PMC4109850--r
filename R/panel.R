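#' Multi-state expression panel
#'
#' Per-state blocks of expression data over one shared, ordered gene list.
#' Each block is an `n_t x p` numeric matrix (samples in rows, genes in
#' columns, log2 scale by convention). All blocks share the same genes in the
#' same order; all values must be finite. A block may hold a single sample
#' for storage, but fitting requires at least two samples per state.
#'
#' @param blocks named list (state -> samples x genes matrix). Matrices must
#'   have column names (genes) and row names (sample ids).
#' @param genes optional gene order to enforce; defaults to the columns of
#'   the first block.
#' @return an object of class `expression_panel` with fields `genes`,
#'   `states`, `blocks`, `sample_ids`.
#' @export
expression_panel <- function(blocks, genes = NULL) {
  if (!is.list(blocks) || is.null(names(blocks)) || any(!nzchar(names(blocks)))) {
    stop("`blocks` must be a named list of matrices")
  }
  if (anyDuplicated(names(blocks))) stop("duplicate state names in `blocks`")
  blocks <- lapply(blocks, function(b) {
    b <- as.matrix(b)
    storage.mode(b) <- "double"
    b
  })
  if (is.null(genes)) genes <- colnames(blocks[[1]])
  if (is.null(genes) || any(!nzchar(genes))) stop("blocks must carry gene column names")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  for (s in names(blocks)) {
    b <- blocks[[s]]
    if (is.null(colnames(b)) || !identical(colnames(b), as.character(genes))) {
      if (!is.null(colnames(b)) && setequal(colnames(b), genes)) {
        blocks[[s]] <- b[, genes, drop = FALSE]
      } else {
        stop("state '", s, "' does not cover the shared gene list")
      }
    }
    if (nrow(blocks[[s]]) < 1L) stop("state '", s, "' has no samples")
    if (!all(is.finite(blocks[[s]]))) stop("non-finite expression value in state '", s, "'")
  }
  structure(
    list(genes = as.character(genes),
         states = names(blocks),
         blocks = blocks,
         sample_ids = lapply(blocks, rownames)),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("<expression_panel> ", length(x$genes), " genes, ",
      length(x$states), " states (n = ",
      paste(vapply(x$blocks, nrow, 0L), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Number of samples per state
#' @param panel an [expression_panel()].
#' @return named integer vector.
#' @export
panel_n <- function(panel) {
  vapply(panel$blocks, nrow, 0L)
}

#' Read an expression panel from TSV files
#'
#' The expression TSV has a header of sample ids, a first column of gene ids,
#' and one row per gene. The sample map TSV has columns `sample_id` and
#' `state`. Samples are partitioned into per-state blocks; gene order is the
#' file order. Every sample in the matrix must be mapped and every mapped
#' sample must be present in the matrix.
#'
#' @param expr_path path to the genes x samples expression TSV.
#' @param samplemap_path path to the sample map TSV.
#' @return an [expression_panel()].
#' @export
read_panel <- function(expr_path, samplemap_path) {
  expr <- read.delim(expr_path, header = TRUE, check.names = FALSE,
                     colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(expr) < 2L) stop("expression TSV must have a gene column plus samples")
  genes <- expr[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene IDs: ", paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  vals <- as.matrix(expr[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = dimnames(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at gene '", genes[bad[1]],
         "', sample '", colnames(vals)[bad[2]], "'")
  }
  rownames(num) <- genes

  map <- read.delim(samplemap_path, header = TRUE, colClasses = "character",
                    stringsAsFactors = FALSE)
  need <- c("sample_id", "state")
  if (!all(need %in% names(map))) {
    stop("sample map must have columns: ", paste(need, collapse = ", "))
  }
  missing_in_matrix <- setdiff(map$sample_id, colnames(num))
  if (length(missing_in_matrix) > 0L) {
    stop("sample(s) in map absent from matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  }
  unmapped <- setdiff(colnames(num), map$sample_id)
  if (length(unmapped) > 0L) {
    stop("unmapped sample(s) in matrix: ", paste(unmapped, collapse = ", "))
  }
  if (anyDuplicated(map$sample_id)) stop("duplicate sample ids in map")
  states <- unique(map$state)
  blocks <- lapply(states, function(s) {
    ids <- map$sample_id[map$state == s]
    t(num[, ids, drop = FALSE])
  })
  names(blocks) <- states
  expression_panel(blocks, genes = genes)
}

#' Write an expression panel to TSV files
#'
#' Inverse of [read_panel()]; values are written with 17 significant digits
#' so a read/write round trip is lossless.
#'
#' @param panel an [expression_panel()].
#' @param expr_path output path for the genes x samples TSV.
#' @param samplemap_path output path for the sample map TSV.
#' @return `expr_path`, invisibly.
#' @export
write_panel <- function(panel, expr_path, samplemap_path) {
  stopifnot(inherits(panel, "expression_panel"))
  mats <- lapply(panel$states, function(s) t(panel$blocks[[s]]))
  full <- do.call(cbind, mats)
  if (is.null(colnames(full)) || any(!nzchar(colnames(full)))) {
    stop("panel blocks must carry sample ids (row names) to be written")
  }
  chr <- matrix(num_chr(full), nrow = nrow(full), dimnames = dimnames(full))
  df <- data.frame(gene_id = panel$genes, chr, check.names = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  map <- data.frame(
    sample_id = unlist(lapply(panel$states, function(s) rownames(panel$blocks[[s]]))),
    state = rep(panel$states, vapply(panel$blocks[panel$states], nrow, 0L))
  )
  write.table(map, samplemap_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}

# reorder panel states to match a tree's canonical (topological) order
align_panel_states <- function(panel, tree) {
  if (!setequal(panel$states, tree$states)) {
    stop("panel states do not match tree states")
  }
  if (identical(panel$states, tree$states)) return(panel)
  expression_panel(panel$blocks[tree$states], genes = panel$genes)
}
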