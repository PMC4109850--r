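#' Generate a random root network
#'
#' Draws a simple undirected graph on `p` nodes with exactly `2p` edges
#' (average degree 4) and maximum degree 6, by uniform rejection: a uniformly
#' random candidate pair is accepted when it is not yet an edge and both
#' endpoints have degree below the cap. If the sampler paints itself into a
#' corner (no acceptance within `10 * p^2` consecutive draws) it restarts
#' from scratch.
#'
#' @param p number of nodes (at least 5, so that 2p edges fit).
#' @param seed optional integer seed.
#' @param max_degree degree cap (default 6).
#' @return symmetric logical adjacency matrix with zero diagonal and node
#'   names `g1..gp`.
#' @export
generate_root_network <- function(p, seed = NULL, max_degree = 6L) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 4)
  p <- as.integer(p)
  n_edges <- 2L * p
  if (n_edges > p * (p - 1L) / 2L || 2 * n_edges > p * max_degree) {
    stop("p = ", p, " cannot host ", n_edges, " edges under the degree cap")
  }
  with_seed(seed, {
    repeat {
      adj <- matrix(FALSE, p, p)
      deg <- integer(p)
      got <- 0L
      fails <- 0L
      stuck <- FALSE
      while (got < n_edges) {
        ij <- sample.int(p, 2L)
        i <- ij[1]; j <- ij[2]
        if (!adj[i, j] && deg[i] < max_degree && deg[j] < max_degree) {
          adj[i, j] <- adj[j, i] <- TRUE
          deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
          got <- got + 1L
          fails <- 0L
        } else {
          fails <- fails + 1L
          if (fails > 10L * p * p) { stuck <- TRUE; break }
        }
      }
      if (!stuck) break
    }
    dimnames(adj) <- list(paste0("g", seq_len(p)), paste0("g", seq_len(p)))
    adj
  })
}

# list of (i, j) index pairs (i < j) of the upper-triangular support
adj_pairs <- function(adj) {
  which(adj & upper.tri(adj), arr.ind = TRUE)
}

#' Rewire a child network from its parent
#'
#' A branching event: `k = round(fraction * E)` of the parent's edges are
#' deleted uniformly at random and `k` new edges are added uniformly among
#' the pairs that are non-edges of the parent, subject to the degree cap.
#' Edge count is conserved and the child shares exactly `E - k` edges with
#' the parent. Additions are drawn uniformly from the currently feasible
#' candidate set; if that set empties before `k` additions the whole attempt
#' is redrawn (bounded retries).
#'
#' @param parent_adj parent adjacency (symmetric logical, zero diagonal).
#' @param fraction fraction of edges to rewire, in `[0, 1]` (default 0.25).
#' @param seed optional integer seed.
#' @param max_degree degree cap (default 6).
#' @param max_attempts bound on full redraws before giving up.
#' @return adjacency matrix of the child network.
#' @export
rewire_child <- function(parent_adj, fraction = 0.25, seed = NULL,
                         max_degree = 6L, max_attempts = 50L) {
  check_adjacency(parent_adj)
  stopifnot(fraction >= 0, fraction <= 1)
  pairs <- adj_pairs(parent_adj)
  E <- nrow(pairs)
  k <- round(fraction * E)  # round-half-to-even, as in base R
  if (k == 0L) return(parent_adj)
  p <- nrow(parent_adj)
  with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      drop_idx <- sample.int(E, k)
      adj <- parent_adj
      for (r in drop_idx) adj[pairs[r, 1], pairs[r, 2]] <- adj[pairs[r, 2], pairs[r, 1]] <- FALSE
      deg <- rowSums(adj)
      # candidate additions: non-edges of the PARENT (so deleted edges never
      # return and parent/child overlap is exactly E - k)
      cand <- which(!parent_adj & upper.tri(parent_adj), arr.ind = TRUE)
      ok <- TRUE
      for (a in seq_len(k)) {
        feas <- deg[cand[, 1]] < max_degree & deg[cand[, 2]] < max_degree
        idx <- which(feas)
        if (length(idx) == 0L) { ok <- FALSE; break }
        pick <- idx[sample.int(length(idx), 1L)]
        i <- cand[pick, 1]; j <- cand[pick, 2]
        adj[i, j] <- adj[j, i] <- TRUE
        deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
        cand <- cand[-pick, , drop = FALSE]
      }
      if (ok) return(adj)
    }
    stop("no feasible edge addition under the degree cap after ",
         max_attempts, " attempts (p = ", p, ", k = ", k, ")")
  })
}

check_adjacency <- function(adj) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (!is.logical(adj)) stop("adjacency must be logical")
  if (any(diag(adj))) stop("adjacency must have an empty diagonal")
  if (!identical(adj, t(adj))) stop("adjacency must be symmetric")
  invisible(adj)
}

#' Convert an adjacency matrix to a positive-definite precision matrix
#'
#' Off-diagonal entries are nonzero exactly on the adjacency support, with
#' magnitudes uniform in `[weight_low, weight_high]` and random signs, drawn
#' symmetrically. The diagonal is set to the row-wise sum of absolute
#' off-diagonal entries plus 0.1, giving strict diagonal dominance and hence
#' positive definiteness.
#'
#' @param adj symmetric logical adjacency, zero diagonal.
#' @param weight_low,weight_high magnitude range, `0 < low <= high`.
#' @param seed optional integer seed.
#' @return symmetric positive-definite precision matrix.
#' @export
adjacency_to_precision <- function(adj, weight_low = 0.2, weight_high = 0.4,
                                   seed = NULL) {
  check_adjacency(adj)
  stopifnot(weight_low > 0, weight_low <= weight_high)
  p <- nrow(adj)
  with_seed(seed, {
    omega <- matrix(0, p, p, dimnames = dimnames(adj))
    up <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(up) > 0L) {
      w <- runif(nrow(up), weight_low, weight_high) *
        sample(c(-1, 1), nrow(up), replace = TRUE)
      omega[up] <- w
      omega[up[, c(2, 1), drop = FALSE]] <- w
    }
    diag(omega) <- rowSums(abs(omega)) + 0.1
    omega
  })
}

#' Construct and validate a collection of true networks
#'
#' Ground truth for simulation: distinct adjacency matrices with matching
#' positive-definite precision matrices, a state-to-network map, and the
#' state tree. Validates that each precision's off-diagonal support equals
#' its adjacency, that precisions are symmetric positive definite, and that
#' the states mapped to one distinct network form a contiguous segment of
#' the tree (each non-head state's parent maps to the same network).
#'
#' @param distinct_networks named list of adjacency matrices.
#' @param precisions matching named list of precision matrices.
#' @param state_map named integer vector: state -> distinct-network index.
#' @param tree a [state_tree()] over `names(state_map)`.
#' @return an object of class `true_network_collection`.
#' @export
true_network_collection <- function(distinct_networks, precisions, state_map,
                                    tree) {
  stopifnot(inherits(tree, "state_tree"),
            length(distinct_networks) == length(precisions))
  if (!setequal(names(state_map), tree$states)) {
    stop("state_map must cover exactly the tree's states")
  }
  for (i in seq_along(distinct_networks)) {
    adj <- check_adjacency(distinct_networks[[i]])
    om <- precisions[[i]]
    if (!isTRUE(all.equal(om, t(om)))) stop("precision ", i, " not symmetric")
    supp <- om != 0
    diag(supp) <- FALSE
    if (!identical(unname(supp), unname(adj))) {
      stop("precision ", i, " support does not match its adjacency")
    }
    if (min(eigen(om, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop("precision ", i, " is not positive definite")
    }
  }
  if (any(state_map < 1L | state_map > length(distinct_networks))) {
    stop("state_map index out of range")
  }
  for (s in tree$states) {
    par <- tree$parent[[s]]
    if (is.na(par)) next
    # contiguity: within a segment every non-head state chains to a state of
    # the same network; a segment head may attach to any other segment
    same <- state_map[[s]] == state_map[[par]]
    heads <- !duplicated(state_map[tree$states])
    names(heads) <- tree$states
    if (!same && !heads[[s]]) {
      stop("states of network ", state_map[[s]], " are not contiguous in the tree")
    }
  }
  structure(
    list(distinct_networks = distinct_networks, precisions = precisions,
         state_map = state_map, tree = tree,
         genes = rownames(distinct_networks[[1]])),
    class = "true_network_collection"
  )
}

#' Build the tree-related collection of true networks
#'
#' Reproduces the simulation protocol: a root network `A` (average degree 4,
#' maximum degree 6, `2p` edges) branches into `B` and `C`, which branch into
#' `D`,`E` and `F`,`G`; each branching rewires 25% of the edges. Each of the
#' 7 distinct networks is held fixed along a segment of `segment_len`
#' consecutive states (segment order A,B,C,D,E,F,G), so `segment_len = 10`
#' gives the canonical 70-state collection. The state tree chains the states
#' within a segment and attaches each segment head to the last state of the
#' parent segment.
#'
#' @param p number of genes (nodes).
#' @param segment_len states per distinct network (>= 1).
#' @param seed optional integer seed.
#' @param rewire_fraction fraction of edges rewired at each branching.
#' @param weight_low,weight_high precision off-diagonal magnitude range.
#' @return an object of class `true_network_collection` with fields
#'   `distinct_networks` (named list of adjacencies A..G), `precisions`,
#'   `state_map` (named integer: state -> distinct-network index), `tree`
#'   (a [state_tree()]), and `genes`.
#' @export
build_tree_collection <- function(p, segment_len = 10L, seed = NULL,
                                  rewire_fraction = 0.25,
                                  weight_low = 0.2, weight_high = 0.4) {
  stopifnot(p >= 4, segment_len >= 1)
  segment_len <- as.integer(segment_len)
  with_seed(seed, {
    A <- generate_root_network(p)
    B <- rewire_child(A, rewire_fraction)
    C <- rewire_child(A, rewire_fraction)
    D <- rewire_child(B, rewire_fraction)
    E <- rewire_child(B, rewire_fraction)
    F <- rewire_child(C, rewire_fraction)
    G <- rewire_child(C, rewire_fraction)
    nets <- list(A = A, B = B, C = C, D = D, E = E, F = F, G = G)
    precisions <- lapply(nets, adjacency_to_precision,
                         weight_low = weight_low, weight_high = weight_high)

    n_states <- 7L * segment_len
    states <- sprintf("s%d", seq_len(n_states))
    state_map <- rep(seq_len(7L), each = segment_len)
    names(state_map) <- states
    # parent of each distinct segment in the branching diagram (A has none)
    seg_parent <- c(A = NA, B = 1L, C = 1L, D = 2L, E = 2L, F = 3L, G = 3L)
    parent <- character(n_states)
    for (i in seq_len(n_states)) {
      seg <- state_map[i]
      pos <- (i - 1L) %% segment_len + 1L
      if (pos > 1L) {
        parent[i] <- states[i - 1L]
      } else if (is.na(seg_parent[seg])) {
        parent[i] <- NA_character_
      } else {
        parent[i] <- states[seg_parent[seg] * segment_len]  # last state of parent segment
      }
    }
    names(parent) <- states
    tree <- state_tree(parent, states = states)
    true_network_collection(nets, precisions, state_map, tree)
  })
}

#' @export
print.true_network_collection <- function(x, ...) {
  cat("<true_network_collection> ", length(x$state_map), " states, ",
      length(x$distinct_networks), " distinct networks, p = ",
      length(x$genes), "\n", sep = "")
  invisible(x)
}

#' True adjacency for a given state
#' @param collection a [build_tree_collection()] result.
#' @param state state identifier.
#' @return logical adjacency matrix.
#' @export
true_adjacency <- function(collection, state) {
  idx <- collection$state_map[[state]]
  collection$distinct_networks[[idx]]
}

#' Draw Gaussian samples from every state's true network
#'
#' For each state, `n_per_state` i.i.d. draws from the zero-mean multivariate
#' normal whose covariance is the inverse of that state's precision matrix.
#'
#' @param collection a [build_tree_collection()] result.
#' @param n_per_state samples per state (>= 1).
#' @param seed optional integer seed.
#' @return an [expression_panel()] with states in tree order.
#' @export
sample_panel <- function(collection, n_per_state, seed = NULL) {
  stopifnot(inherits(collection, "true_network_collection"))
  if (!is.numeric(n_per_state) || n_per_state < 1) {
    stop("`n_per_state` must be at least 1")
  }
  n_per_state <- as.integer(n_per_state)
  genes <- collection$genes
  p <- length(genes)
  with_seed(seed, {
    # one upper Cholesky of the covariance per distinct network
    chols <- lapply(collection$precisions, function(om) chol(solve(om)))
    blocks <- lapply(collection$tree$states, function(s) {
      R <- chols[[collection$state_map[[s]]]]
      z <- matrix(rnorm(n_per_state * p), n_per_state, p)
      x <- z %*% R
      dimnames(x) <- list(paste0(s, "_r", seq_len(n_per_state)), genes)
      x
    })
    names(blocks) <- collection$tree$states
    expression_panel(blocks, genes = genes)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits the panel TSV + sample map, the state tree TSV, and one ground-truth
#' edge list per distinct network (TSV: gene_i, gene_j in canonical order).
#'
#' @param collection a [build_tree_collection()] result.
#' @param panel an [expression_panel()] from [sample_panel()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(collection, panel, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_panel(panel, file.path(out_dir, "panel.tsv"),
              file.path(out_dir, "samples.tsv"))
  write_tree(collection$tree, file.path(out_dir, "tree.tsv"))
  for (nm in names(collection$distinct_networks)) {
    adj <- collection$distinct_networks[[nm]]
    up <- adj_pairs(adj)
    g <- rownames(adj)
    keys <- sort(edge_keys(g[up[, 1]], g[up[, 2]]))
    df <- split_edge_keys(keys)
    write.table(df, file.path(out_dir, paste0("truth_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
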