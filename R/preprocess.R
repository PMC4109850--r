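#' Probe-level intensity matrix
#'
#' Perfect-match probe intensities (probes x arrays) plus a probe-to-gene
#' map. Intensities are positive on the linear scale; after normalization
#' the object carries log2-scale values.
#'
#' @param values probes x arrays numeric matrix with probe row names and
#'   array column names.
#' @param probe_gene named character vector: probe id -> gene id (every probe
#'   maps to exactly one gene).
#' @param log2_scale `FALSE` for raw linear intensities (default).
#' @return an object of class `probe_matrix`.
#' @export
probe_matrix <- function(values, probe_gene, log2_scale = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("probe matrix needs probe row names")
  if (!all(rownames(values) %in% names(probe_gene))) {
    stop("every probe must map to exactly one gene")
  }
  if (!all(is.finite(values))) stop("intensities must be finite")
  if (!log2_scale && any(values <= 0)) {
    stop("linear-scale intensities must be positive")
  }
  structure(list(values = values,
                 probe_gene = probe_gene[rownames(values)],
                 log2_scale = isTRUE(log2_scale)),
            class = "probe_matrix")
}

#' @export
print.probe_matrix <- function(x, ...) {
  cat("<probe_matrix> ", nrow(x$values), " probes x ", ncol(x$values),
      " arrays (", if (x$log2_scale) "log2" else "linear", " scale), ",
      length(unique(x$probe_gene)), " genes\n", sep = "")
  invisible(x)
}

#' Read a probe-level TSV
#'
#' Columns: `probe_id`, `gene_id`, then one column per array.
#' @param path TSV path.
#' @param log2_scale whether the stored values are already log2.
#' @return a [probe_matrix()].
#' @export
read_probe_matrix <- function(path, log2_scale = FALSE) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(df)[1:2])) {
    stop("probe TSV must start with columns probe_id, gene_id")
  }
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$probe_id
  probe_matrix(vals, setNames(df$gene_id, df$probe_id), log2_scale)
}

#' Log2 transform and cyclic loess normalization
#'
#' Probe intensities are log2-transformed, then normalized by cyclic loess:
#' for every array pair (i, j), a lowess curve of the log-ratio
#' `M = x_i - x_j` on the average `A = (x_i + x_j) / 2` is fitted and half
#' the fitted trend is subtracted from array i and added to array j. All
#' pairs are visited for a fixed number of cycles.
#'
#' @param pm a [probe_matrix()] on the linear scale.
#' @param span lowess span (default 0.7).
#' @param cycles full passes over all array pairs (default 2).
#' @return a [probe_matrix()] on the log2 scale, normalized.
#' @export
normalize_probe_matrix <- function(pm, span = 0.7, cycles = 2L) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (pm$log2_scale) stop("probe matrix is already on the log2 scale")
  if (any(pm$values <= 0)) stop("nonpositive intensity")
  x <- log2(pm$values)
  n_arr <- ncol(x)
  if (n_arr >= 2L) {
    for (cyc in seq_len(cycles)) {
      for (i in seq_len(n_arr - 1L)) {
        for (j in seq.int(i + 1L, n_arr)) {
          M <- x[, i] - x[, j]
          A <- (x[, i] + x[, j]) / 2
          lo <- lowess(A, M, f = span)
          fit <- approx(lo$x, lo$y, xout = A, rule = 2, ties = mean)$y
          x[, i] <- x[, i] - fit / 2
          x[, j] <- x[, j] + fit / 2
        }
      }
    }
  }
  probe_matrix(x, pm$probe_gene, log2_scale = TRUE)
}

# Tukey median polish of one probes x arrays block; returns the per-array
# summary (overall + column effect) with the decomposition as attributes
polish_block <- function(block, tol = 1e-4, max_iter = 10L) {
  t_all <- 0
  r <- numeric(nrow(block))
  c_eff <- numeric(ncol(block))
  res <- block
  for (it in seq_len(max_iter)) {
    rm_ <- apply(res, 1L, median)
    r <- r + rm_
    res <- res - rm_
    dc <- median(c_eff)
    c_eff <- c_eff - dc
    t_all <- t_all + dc
    cm_ <- apply(res, 2L, median)
    c_eff <- c_eff + cm_
    res <- sweep(res, 2L, cm_)
    dr <- median(r)
    r <- r - dr
    t_all <- t_all + dr
    if (max(abs(rm_)) < tol && max(abs(cm_)) < tol) break
  }
  structure(t_all + c_eff,
            overall = t_all, row_effects = r, col_effects = c_eff,
            residuals = res)
}

#' Summarize probes into gene expression by median polish
#'
#' For each gene, its probes x arrays block is decomposed into overall, row
#' (probe) and column (array) effects by Tukey's median polish (row and
#' column medians removed alternately until the largest adjustment falls
#' below `tol`, capped at `max_iter` sweeps). The gene's value on an array
#' is the overall effect plus that array's column effect.
#'
#' @param pm a [probe_matrix()] on the log2 scale.
#' @param tol convergence tolerance on the median adjustments (default 1e-4).
#' @param max_iter sweep cap (default 10).
#' @return genes x arrays numeric matrix (row names are gene ids, ordered by
#'   first appearance in the probe map).
#' @export
median_polish_summarize <- function(pm, tol = 1e-4, max_iter = 10L) {
  stopifnot(inherits(pm, "probe_matrix"))
  if (!pm$log2_scale) stop("median polish expects a log2-scale probe matrix")
  genes <- unique(unname(pm$probe_gene))
  out <- matrix(NA_real_, length(genes), ncol(pm$values),
                dimnames = list(genes, colnames(pm$values)))
  for (g in genes) {
    rows <- which(pm$probe_gene == g)
    if (length(rows) == 0L) {
      warning("gene '", g, "' has no probes; skipped")
      next
    }
    block <- pm$values[rows, , drop = FALSE]
    out[g, ] <- if (nrow(block) == 1L) as.numeric(block) else
      polish_block(block, tol = tol, max_iter = max_iter)
  }
  out[!is.na(out[, 1L]), , drop = FALSE]
}

#' Collapse duplicate gene rows by per-array median
#'
#' Rows sharing a gene id (row name) are replaced by their element-wise
#' median; unique rows pass through unchanged. Row order is the order of
#' first appearance.
#'
#' @param expr genes x arrays matrix, possibly with repeated row names.
#' @return matrix with unique row names.
#' @export
collapse_duplicates <- function(expr) {
  expr <- as.matrix(expr)
  ids <- rownames(expr)
  if (is.null(ids)) stop("expression matrix needs gene row names")
  if (!anyDuplicated(ids)) return(expr)
  genes <- unique(ids)
  out <- matrix(NA_real_, length(genes), ncol(expr),
                dimnames = list(genes, colnames(expr)))
  for (g in genes) {
    rows <- expr[ids == g, , drop = FALSE]
    out[g, ] <- if (nrow(rows) == 1L) rows else apply(rows, 2L, median)
  }
  out
}

#' Gene-variability (fold-change) filter
#'
#' For each gene, the median log2 expression is computed within every state;
#' the gene is retained when the largest between-state fold change,
#' `2^|median_a - median_b|`, exceeds `threshold`. The published analysis
#' used 1.3, which retained 5,440 of 12,977 genes.
#'
#' @param panel an [expression_panel()] on the log2 scale.
#' @param threshold linear-scale fold-change threshold, must be > 1.
#' @return the filtered [expression_panel()] (genes subset, original order).
#' @export
fold_change_filter <- function(panel, threshold = 1.3) {
  stopifnot(inherits(panel, "expression_panel"))
  if (!is.numeric(threshold) || threshold <= 1) {
    stop("fold-change threshold must be > 1")
  }
  med <- vapply(panel$blocks, function(b) apply(b, 2L, median),
                numeric(length(panel$genes)))
  med <- matrix(med, nrow = length(panel$genes))
  span <- apply(med, 1L, function(v) diff(range(v)))
  keep <- span > log2(threshold)
  blocks <- lapply(panel$blocks, function(b) b[, keep, drop = FALSE])
  expression_panel(blocks, genes = panel$genes[keep])
}
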