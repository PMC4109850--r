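#' Per-state gene network
#'
#' A weighted undirected graph over the gene universe: edges are stored once
#' in canonical (lexicographic) pair order with signed nonzero weights.
#'
#' @param state state identifier.
#' @param genes gene universe (character vector).
#' @param edges data.frame with columns `gene_i`, `gene_j`, `weight`.
#' @return an object of class `gene_network`.
#' @export
gene_network <- function(state, genes, edges) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(gene_i = character(), gene_j = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("gene_i", "gene_j", "weight") %in% names(edges))) {
      stop("edges must have columns gene_i, gene_j, weight")
    }
    if (any(edges$gene_i == edges$gene_j)) stop("self loops are not allowed")
    bad <- setdiff(c(edges$gene_i, edges$gene_j), genes)
    if (length(bad) > 0L) stop("edge references unknown gene: ",
                               paste(unique(bad), collapse = ", "))
    if (any(edges$weight == 0) || !all(is.finite(edges$weight))) {
      stop("edge weights must be finite and nonzero")
    }
    swap <- edges$gene_i > edges$gene_j
    tmp <- edges$gene_i[swap]
    edges$gene_i[swap] <- edges$gene_j[swap]
    edges$gene_j[swap] <- tmp
    if (anyDuplicated(paste(edges$gene_i, edges$gene_j, sep = "\t"))) {
      stop("duplicate edges")
    }
    edges <- edges[order(edges$gene_i, edges$gene_j), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(state = state, genes = genes, edges = edges),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> state '", x$state, "': ", nrow(x$edges), " edges over ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

network_edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(net$edges$gene_i, net$edges$gene_j, sep = "\t")
}

#' Max-symmetrization of neighborhood coefficients
#'
#' An edge (i, j) is present when either directional coefficient
#' `B[i, j]` or `B[j, i]` is nonzero; its weight is whichever of the two has
#' the larger absolute value (on a tie, `B[i, j]` with `i` before `j` in
#' canonical gene order).
#'
#' @param x a [coefficient_tensor()] (returns one network per state) or a
#'   single `p x p` coefficient matrix with gene dimnames.
#' @param ... unused.
#' @return a named list of [gene_network()] for tensors; a single
#'   [gene_network()] for matrices.
#' @export
symmetrize_max <- function(x, ...) UseMethod("symmetrize_max")

#' @rdname symmetrize_max
#' @param state state label used for matrix input.
#' @export
symmetrize_max.matrix <- function(x, state = "state", ...) {
  genes <- rownames(x)
  if (is.null(genes) || !identical(genes, colnames(x))) {
    stop("coefficient matrix must have matching gene dimnames")
  }
  tx <- t(x)
  use_t <- abs(tx) > abs(x)     # strictly larger magnitude wins; ties keep B[i,j]
  w <- ifelse(use_t, tx, x)
  present <- (x != 0 | tx != 0) & upper.tri(x)
  idx <- which(present, arr.ind = TRUE)
  edges <- data.frame(gene_i = genes[idx[, 1]], gene_j = genes[idx[, 2]],
                      weight = w[idx], stringsAsFactors = FALSE)
  gene_network(state, genes, edges)
}

#' @rdname symmetrize_max
#' @export
symmetrize_max.coefficient_tensor <- function(x, ...) {
  out <- lapply(x$states, function(s) symmetrize_max(x$beta[[s]], state = s))
  names(out) <- x$states
  out
}

#' Filter network edges
#'
#' `abs_threshold` keeps edges with `|w| > threshold` (the display rule used
#' for network figures, default cut-off 0.1); `positive_only` keeps `w > 0`
#' (the interpretation rule used for hubs and enrichment input).
#'
#' @param net a [gene_network()].
#' @param mode `"abs_threshold"` or `"positive_only"`.
#' @param threshold nonnegative threshold for `abs_threshold` mode.
#' @return a filtered [gene_network()].
#' @export
filter_edges <- function(net, mode = c("abs_threshold", "positive_only"),
                         threshold = 0.1) {
  stopifnot(inherits(net, "gene_network"))
  mode <- match.arg(mode)
  if (threshold < 0) stop("threshold must be nonnegative")
  keep <- switch(mode,
    abs_threshold = abs(net$edges$weight) > threshold,
    positive_only = net$edges$weight > 0
  )
  gene_network(net$state, net$genes, net$edges[keep, , drop = FALSE])
}

#' Shared and differential edge sets
#'
#' `shared` holds the edges present (by unordered pair, ignoring weights) in
#' every supplied network; `differential[[s]]` holds the edges of state `s`
#' present in no other state's network. In the breast-cell analysis the
#' differential networks are the state-specific rewiring on top of the ~60%
#' of edges common to all states.
#'
#' @param nets list of at least two [gene_network()] over one gene universe.
#' @return an object of class `differential_set`: list with `shared`
#'   (data.frame gene_i, gene_j) and `differential` (named list of
#'   data.frames).
#' @export
shared_and_differential <- function(nets) {
  if (length(nets) < 2L) stop("need at least 2 networks")
  uni <- nets[[1]]$genes
  for (nt in nets) {
    if (!setequal(nt$genes, uni)) stop("networks have different gene universes")
  }
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- vapply(nets, function(x) x$state, "")
  }
  keysets <- lapply(nets, network_edge_keys)
  shared <- Reduce(intersect, keysets)
  differential <- lapply(seq_along(nets), function(i) {
    others <- unique(unlist(keysets[-i]))
    split_edge_keys(setdiff(keysets[[i]], others))
  })
  names(differential) <- names(nets)
  structure(list(shared = split_edge_keys(sort(shared)),
                 differential = differential),
            class = "differential_set")
}

#' @export
print.differential_set <- function(x, ...) {
  cat("<differential_set> shared:", nrow(x$shared), "edges; differential:",
      paste(sprintf("%s=%d", names(x$differential),
                    vapply(x$differential, nrow, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' The per-state differential network as a gene_network
#'
#' Convenience accessor: restricts a state's network to its differential
#' edges (weights retained from the state's own network).
#'
#' @param nets named list of [gene_network()].
#' @param dset result of [shared_and_differential()] on `nets`.
#' @param state state to extract.
#' @return a [gene_network()].
#' @export
differential_network <- function(nets, dset, state) {
  net <- nets[[state]]
  if (is.null(net)) stop("unknown state: ", state)
  dk <- dset$differential[[state]]
  keep <- paste(net$edges$gene_i, net$edges$gene_j, sep = "\t") %in%
    paste(dk$gene_i, dk$gene_j, sep = "\t")
  gene_network(net$state, net$genes, net$edges[keep, , drop = FALSE])
}

#' Hub genes of a network
#'
#' Degree is the number of incident edges, restricted to positive-weight
#' edges when `positive_only` is set (the convention for the differential
#' networks). Hubs are genes with degree strictly greater than the
#' threshold, sorted by decreasing degree then gene id.
#'
#' @param net a [gene_network()].
#' @param degree_threshold nonnegative integer (default 5).
#' @param positive_only count only positive-weight edges (default `TRUE`).
#' @return data.frame with columns `gene`, `degree`.
#' @export
hubs <- function(net, degree_threshold = 5L, positive_only = TRUE) {
  stopifnot(inherits(net, "gene_network"), degree_threshold >= 0)
  ed <- net$edges
  if (positive_only) ed <- ed[ed$weight > 0, , drop = FALSE]
  deg <- table(factor(c(ed$gene_i, ed$gene_j), levels = net$genes))
  deg <- deg[deg > degree_threshold]
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neighborhood subnetwork of a gene
#'
#' The subgraph induced on the gene and its direct neighbors, including
#' neighbor-neighbor edges.
#'
#' @param net a [gene_network()].
#' @param gene a gene in the network's universe.
#' @return a [gene_network()] over the member genes.
#' @export
hub_neighborhood <- function(net, gene) {
  stopifnot(inherits(net, "gene_network"))
  if (!gene %in% net$genes) stop("unknown gene: ", gene)
  ed <- net$edges
  nb <- unique(c(ed$gene_j[ed$gene_i == gene], ed$gene_i[ed$gene_j == gene]))
  members <- union(gene, nb)
  keep <- ed$gene_i %in% members & ed$gene_j %in% members
  gene_network(net$state, members[order(members)], ed[keep, , drop = FALSE])
}

#' Write networks to an edge-list TSV
#'
#' Columns `state`, `gene_i`, `gene_j`, `weight`; pairs canonical
#' (`gene_i < gene_j` lexicographically), rows ordered by state (input list
#' order) then pair. Weights keep full precision for lossless round trips.
#'
#' @param networks list of [gene_network()].
#' @param out_path output path.
#' @return `out_path`, invisibly.
#' @export
write_networks <- function(networks, out_path) {
  if (inherits(networks, "gene_network")) networks <- list(networks)
  rows <- lapply(networks, function(nt) {
    stopifnot(inherits(nt, "gene_network"))
    if (nrow(nt$edges) == 0L) return(NULL)
    data.frame(state = nt$state, nt$edges, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(state = character(), gene_i = character(),
                     gene_j = character(), weight = character())
  } else {
    df$weight <- num_chr(df$weight)
  }
  write.table(df, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Read networks from an edge-list TSV
#'
#' Inverse of [write_networks()]. The gene universe of each network is taken
#' from `genes` when supplied, otherwise from the genes seen in the file.
#'
#' @param path edge-list TSV path.
#' @param genes optional gene universe shared by all networks.
#' @return named list of [gene_network()] (possibly empty).
#' @export
read_networks <- function(path, genes = NULL) {
  df <- read.delim(path, header = TRUE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (!all(c("state", "gene_i", "gene_j", "weight") %in% names(df))) {
    stop("network file must have columns state, gene_i, gene_j, weight")
  }
  if (nrow(df) == 0L) return(list())
  if (is.null(genes)) genes <- sort(unique(c(df$gene_i, df$gene_j)))
  states <- unique(df$state)
  out <- lapply(states, function(s) {
    sub <- df[df$state == s, , drop = FALSE]
    gene_network(s, genes,
                 data.frame(gene_i = sub$gene_i, gene_j = sub$gene_j,
                            weight = as.numeric(sub$weight),
                            stringsAsFactors = FALSE))
  })
  names(out) <- states
  out
}
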