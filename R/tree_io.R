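#' Parse a newick string into a validated rooted tree
#'
#' Reads a standard newick string (branch lengths as decimal floats,
#' multifurcations allowed) and returns an [ape::phylo] object that has
#' passed the package's validation rules: a single root, unique non-empty
#' tip labels, and non-negative branch lengths.  Edges whose length is
#' missing from the string are set to 0 with a warning.  The root edge, when
#' the string supplies one (a trailing `:x` before the semicolon), is kept
#' in `$root.edge`; otherwise it is treated as an edge of length 0
#' throughout the package.
#'
#' All phylogenetic diversity computations here use the *rooted* convention:
#' the branch length of a tip set includes the path from the set's most
#' recent common ancestor up to the root (see [induced_pd()]).
#'
#' @param text A newick string.
#' @return A validated `phylo` object.
#' @seealso [read_tree()] for reading from a file, [write_newick()],
#'   [tip_counts()] for per-node descendant-tip counts.
#' @examples
#' tr <- parse_newick("((A:1,B:2):2,(C:1,D:1):1);")
#' total_branch_length(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- withCallingHandlers(
    ape::read.tree(text = text),
    warning = function(w) {
      abort(paste0("newick parse error: ", conditionMessage(w)))
    }
  )
  if (is.null(tr)) abort("newick parse error: unparseable string")
  validate_tree(tr)
}

# cheap pre-scan so malformed input reports a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error at character offset %d: unmatched ')'", i))
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "newick parse error at character offset %d: %d unclosed '('",
      length(chars), depth
    ))
  }
  invisible(TRUE)
}

#' Read and validate a rooted tree from a newick file
#'
#' @param path Path to a newick file (first tree is used).
#' @return A validated `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Validate a rooted tree
#'
#' Checks the invariants every tree consumed by this package must satisfy:
#' class `phylo`, rooted, unique non-empty tip labels, branch lengths
#' present (missing lengths are replaced by 0 with a warning) and
#' non-negative.  Multifurcations and zero-length edges are accepted as-is;
#' trees inferred from amplicon data routinely contain both.
#'
#' @param tree A `phylo` object.
#' @return The tree, possibly with repaired branch lengths, invisibly valid.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo object")
  labs <- tree$tip.label
  if (any(!nzchar(labs))) abort("tree validation error: empty tip label")
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    abort(paste0(
      "tree validation error: duplicate tip label(s): ",
      paste(dup, collapse = ", ")
    ))
  }
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; all set to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  bad <- !is.finite(tree$edge.length)
  if (any(bad)) {
    warn(sprintf("%d missing branch length(s) set to 0", sum(bad)))
    tree$edge.length[bad] <- 0
  }
  if (any(tree$edge.length < 0)) {
    abort("tree validation error: negative branch length")
  }
  if (!is.null(tree$root.edge) && (!is.finite(tree$root.edge) || tree$root.edge < 0)) {
    abort("tree validation error: invalid root edge length")
  }
  # every parsed newick has exactly one root node; a basal multifurcation
  # (ape's "unrooted" flag) is accepted, as in FastTree output
  tree
}

#' Serialize a tree to newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

root_edge_length <- function(tree) {
  if (is.null(tree$root.edge)) 0 else tree$root.edge
}

root_node <- function(tree) ape::Ntip(tree) + 1L

#' Descendant-tip counts for every node
#'
#' For each node (tips first, then internal nodes, in `phylo` numbering)
#' the number of tips descended from, and including, that node; the count
#' attached to a node is the abundance class of the edge directly above it.
#' Optional integer tip weights treat a tip as that many identical
#' individuals.
#'
#' @param tree A `phylo` object.
#' @param weights Optional numeric vector of per-tip weights, either named
#'   by tip label or in `tip.label` order; default 1 for every tip.
#' @return Numeric vector of length `Ntip + Nnode`.
#' @export
tip_counts <- function(tree, weights = NULL) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  w <- rep(1, ntip)
  if (!is.null(weights)) {
    if (!is.null(names(weights))) {
      miss <- setdiff(names(weights), tree$tip.label)
      if (length(miss)) abort(paste0("unknown tip(s) in weights: ", paste(miss, collapse = ", ")))
      w[match(names(weights), tree$tip.label)] <- weights
    } else {
      stopifnot(length(weights) == ntip)
      w <- weights
    }
    if (any(w < 0)) abort("tip weights must be non-negative")
  }
  counts <- c(w, rep(0, nnode))
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    counts[po$edge[i, 1L]] <- counts[po$edge[i, 1L]] + counts[po$edge[i, 2L]]
  }
  counts
}

# Per-edge table used across the package.  One row per edge, child-node
# indexed; the root edge (length $root.edge or 0) is appended last with
# parent NA and abundance class N.
edge_table <- function(tree, weights = NULL) {
  nd <- tip_counts(tree, weights)
  ntip_w <- nd[root_node(tree)]
  if (ape::Ntip(tree) == 1L) ntip_w <- nd[1L]
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  data.frame(
    parent = c(parent, NA_integer_),
    child = c(child, root_node(tree)),
    length = c(tree$edge.length, root_edge_length(tree)),
    n = c(nd[child], ntip_w)
  )
}

#' Total branch length of a tree
#'
#' Sum of all edge lengths, including the root edge when present; the
#' phylogenetic diversity of the complete community.
#'
#' @param tree A `phylo` object.
#' @return Total branch length.
#' @examples
#' total_branch_length(fixture_tree()) # 8
#' @export
total_branch_length <- function(tree) {
  sum(tree$edge.length) + root_edge_length(tree)
}

match_tips <- function(tree, tips, arg = "tips") {
  tips <- unique(as.character(tips))
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0(
      "unknown tip label(s) in ", arg, ": ",
      paste(tips[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

# logical vector over edges of edge_table order (tree edges then root edge):
# TRUE where >= 1 member of `tip_idx` descends through the edge
edge_presence <- function(tree, tip_idx) {
  ntip <- ape::Ntip(tree)
  present <- logical(ntip + tree$Nnode)
  present[tip_idx] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    if (present[po$edge[i, 2L]]) present[po$edge[i, 1L]] <- TRUE
  }
  # map back to input edge order
  c(present[tree$edge[, 2L]], length(tip_idx) > 0L)
}

#' Phylogenetic diversity of an explicit tip set (rooted convention)
#'
#' Sums the length of every edge with at least one member of `tips` among
#' its descendant tips.  This connects the sample to the root: the path
#' from the sample's MRCA up to the root is included, and the root edge
#' (if any) contributes whenever the set is non-empty.  This rooted
#' convention is the one whose expectation the analytic theory computes --
#' [expected_pd()] sums `L(n) * P(n)` over *all* edges -- and differs from
#' PD software that spans only the sample's MRCA subtree.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (may be empty).
#' @return Branch length (0 for the empty set).
#' @examples
#' tr <- fixture_tree()
#' induced_pd(tr, c("A"))            # pendant 1 + internal 2 = 3
#' induced_pd(tr, tr$tip.label)      # total branch length, 8
#' @export
induced_pd <- function(tree, tips) {
  if (length(tips) == 0L) return(0)
  idx <- match_tips(tree, tips)
  pres <- edge_presence(tree, idx)
  lens <- c(tree$edge.length, root_edge_length(tree))
  sum(lens[pres])
}

#' Read a tip-set file
#'
#' One tip label per line; `#` starts a comment; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of tip labels.
#' @export
read_tip_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Read a sample-by-tip membership table
#'
#' TSV with header `sample<TAB>tip`; one row per (sample, tip) pair.
#'
#' @param path File path.
#' @return A tibble with columns `sample` and `tip`.
#' @export
read_membership <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample", "tip") %in% names(df))) {
    abort("membership table must have columns 'sample' and 'tip'")
  }
  dplyr::distinct(df[, c("sample", "tip")])
}
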