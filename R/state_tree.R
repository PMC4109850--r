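#' Phenotypic state tree
#'
#' A rooted tree over cell-state identifiers, plus optional "anchor" pairs
#' (state, ancestor) that receive an extra fusion penalty in the joint fit.
#' In the breast-cell panel the nonmalignant S1 state is the root, the
#' malignant T4-2 state its child, and the three reverted groups are children
#' of T4-2; anchors tie each reverted group back to S1 so the estimates are
#' not biased towards the malignant parent alone.
#'
#' @param parent named character vector mapping each state to its parent;
#'   exactly one entry must be `NA` (the root). Names define the states.
#' @param anchors `NULL`, or a two-column character matrix / data.frame of
#'   (state, ancestor) pairs. With `NULL`, the default rule is applied: every
#'   leaf whose parent is not the root is anchored to the root.
#' @param states optional explicit state order; defaults to a root-first
#'   topological order of `names(parent)`.
#' @return an object of class `state_tree` with fields `states`, `parent`
#'   (named vector, `NA` at the root), `root`, and `anchors` (2-column
#'   character matrix, possibly 0-row).
#' @examples
#' tr <- state_tree(c(S1 = NA, T4 = "S1", R1 = "T4", R2 = "T4"))
#' tr$anchors   # default rule anchors the leaves R1, R2 to S1
#' @export
state_tree <- function(parent, anchors = NULL, states = NULL) {
  if (is.null(names(parent)) || any(!nzchar(names(parent)))) {
    stop("`parent` must be a named vector with non-empty state names")
  }
  nm <- names(parent)
  if (anyDuplicated(nm)) stop("state identifiers must be unique")
  parent <- as.character(parent)
  names(parent) <- nm
  roots <- nm[is.na(parent)]
  if (length(roots) != 1L) {
    stop("exactly one root required, found ", length(roots))
  }
  missing_par <- setdiff(parent[!is.na(parent)], nm)
  if (length(missing_par) > 0L) {
    stop("parent state(s) not declared: ", paste(missing_par, collapse = ", "))
  }
  # root-first topological order; failure to place all states means a cycle
  topo <- roots
  placed <- structure(logical(length(nm)), names = nm)
  placed[roots] <- TRUE
  repeat {
    nxt <- nm[!placed & parent %in% topo]
    if (length(nxt) == 0L) break
    topo <- c(topo, nxt)
    placed[nxt] <- TRUE
  }
  if (!all(placed)) {
    stop("parent map contains a cycle involving: ",
         paste(nm[!placed], collapse = ", "))
  }
  if (!is.null(states)) {
    if (!setequal(states, nm)) stop("`states` must be a permutation of the state names")
    topo <- as.character(states)
  }
  tr <- structure(
    list(states = topo, parent = parent[topo], root = roots, anchors = NULL),
    class = "state_tree"
  )
  if (is.null(anchors)) {
    anchors <- default_anchors(tr)
  } else {
    anchors <- as.matrix(anchors)
    if (ncol(anchors) != 2L && nrow(anchors) > 0L) {
      stop("`anchors` must have two columns (state, ancestor)")
    }
    storage.mode(anchors) <- "character"
    if (nrow(anchors) > 0L) {
      for (i in seq_len(nrow(anchors))) {
        s <- anchors[i, 1]; a <- anchors[i, 2]
        if (!s %in% topo || !a %in% topo) {
          stop("anchor pair references unknown state: ", s, " -> ", a)
        }
        if (!is_ancestor(tr, a, s)) {
          stop("anchor ancestor '", a, "' is not a strict ancestor of '", s, "'")
        }
      }
    }
  }
  if (nrow(anchors) == 0L) {
    anchors <- matrix(character(), ncol = 2L)
  }
  colnames(anchors) <- c("state", "ancestor")
  tr$anchors <- anchors
  tr
}

# TRUE if `a` is a strict ancestor of `s`
is_ancestor <- function(tree, a, s) {
  cur <- tree$parent[[s]]
  while (!is.na(cur)) {
    if (cur == a) return(TRUE)
    cur <- tree$parent[[cur]]
  }
  FALSE
}

default_anchors <- function(tree) {
  leaves <- setdiff(tree$states, tree$parent[!is.na(tree$parent)])
  sel <- leaves[vapply(leaves, function(s) {
    p <- tree$parent[[s]]
    !is.na(p) && p != tree$root
  }, logical(1))]
  if (length(sel) == 0L) return(matrix(character(), ncol = 2L))
  cbind(state = sel, ancestor = rep(tree$root, length(sel)))
}

#' Tree edges as (child, parent) pairs
#' @param tree a [state_tree()].
#' @return two-column character matrix, one row per non-root state.
#' @export
tree_edges <- function(tree) {
  stopifnot(inherits(tree, "state_tree"))
  ch <- tree$states[tree$states != tree$root]
  cbind(child = ch, parent = unname(tree$parent[ch]))
}

#' Fusion pairs: tree edges plus anchor pairs
#'
#' These are the pairs of states whose coefficient vectors are tied by the
#' total-variation penalty in the joint fit.
#' @param tree a [state_tree()].
#' @return two-column character matrix (state, other-state).
#' @export
fusion_pairs <- function(tree) {
  e <- tree_edges(tree)
  colnames(e) <- c("state", "other")
  a <- tree$anchors
  if (nrow(a) > 0L) {
    colnames(a) <- c("state", "other")
    e <- rbind(e, a)
  }
  e
}

#' @export
print.state_tree <- function(x, ...) {
  cat("<state_tree> ", length(x$states), " states, root = ", x$root, "\n", sep = "")
  cat("  edges:", nrow(tree_edges(x)), " anchors:", nrow(x$anchors), "\n")
  invisible(x)
}

#' Read a state tree from a TSV file
#'
#' Each row is `child<TAB>parent` with `-` as the parent of the root, and an
#' optional third column naming an anchor ancestor for that child (`-` or
#' empty for none). If the file has no third column at all, the default
#' anchor rule of [state_tree()] is applied; if the column is present, the
#' anchors listed there are used verbatim (all `-` means "no anchors").
#'
#' @param tree_path path to the tree TSV (no header).
#' @return a [state_tree()].
#' @export
read_tree <- function(tree_path) {
  raw <- read.delim(tree_path, header = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  if (ncol(raw) < 2L) stop("tree file must have at least two columns")
  child <- trimws(raw[[1]]); par <- trimws(raw[[2]])
  if (anyDuplicated(child)) {
    stop("duplicate child rows: ", paste(unique(child[duplicated(child)]), collapse = ", "))
  }
  parent <- ifelse(par == "-" | par == "", NA_character_, par)
  names(parent) <- child
  anchors <- NULL
  if (ncol(raw) >= 3L) {
    anc <- trimws(raw[[3]])
    keep <- !(anc == "-" | anc == "")
    anchors <- cbind(state = child[keep], ancestor = anc[keep])
  }
  state_tree(parent, anchors = anchors)
}

#' Write a state tree to TSV
#'
#' Inverse of [read_tree()]: always writes the three-column form.
#' @param tree a [state_tree()].
#' @param tree_path output path.
#' @return `tree_path`, invisibly.
#' @export
write_tree <- function(tree, tree_path) {
  stopifnot(inherits(tree, "state_tree"))
  anc <- setNames(rep("-", length(tree$states)), tree$states)
  if (nrow(tree$anchors) > 0L) {
    if (anyDuplicated(tree$anchors[, 1])) {
      stop("cannot serialize more than one anchor per state to TSV")
    }
    anc[tree$anchors[, 1]] <- tree$anchors[, 2]
  }
  df <- data.frame(child = tree$states,
                   parent = ifelse(is.na(tree$parent), "-", tree$parent),
                   anchor = unname(anc))
  write.table(df, tree_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(tree_path)
}
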