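#' Parse a Newick string into a validated host phylogeny
#'
#' Thin, validating wrapper around [ape::read.tree()]. The tree must carry
#' branch lengths (interpreted throughout the package as millions of years);
#' tip labels are whitespace-trimmed and must be unique.
#'
#' @param text A Newick string (or a length-1 character vector).
#' @param ultrametric If `TRUE` (default) the tree is required to be
#'   ultrametric: all root-to-tip depths equal within a relative tolerance of
#'   `1e-6`. Published time trees carry rounding error, hence the tolerance.
#' @return An object of class `"phylo"`.
#' @seealso [read_host_tree()] to read from a file, [star_tree()],
#'   [to_vcv()], [branch_segments()].
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_depth(tr) # 2
parse_newick <- function(text, ultrametric = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) {
    stop("Newick parse error: could not parse string starting at position 1: ",
         substr(text, 1, 40), call. = FALSE)
  }
  validate_tree(tree, ultrametric = ultrametric)
}

#' @rdname parse_newick
#' @param path Path to a Newick file.
#' @export
read_host_tree <- function(path, ultrametric = TRUE) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               ultrametric = ultrametric)
}

#' Serialize a phylogeny to a Newick string
#' @param tree A `"phylo"` object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

validate_tree <- function(tree, ultrametric = TRUE) {
  tree$tip.label <- trimws(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; branch lengths (Myr) are required", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (ultrametric) {
    d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
    if (diff(range(d)) > 1e-6 * max(d)) {
      stop("tree is not ultrametric (root-to-tip depths range ",
           signif(min(d), 8), " to ", signif(max(d), 8), ")", call. = FALSE)
    }
  }
  tree
}

# root-to-node path length for every node (tips first, ape numbering)
node_depths <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  depth <- numeric(ntip + nnode)
  # edges of a valid "phylo" are not guaranteed preorder; use reorder
  tr <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + tr$edge.length[k]
  }
  depth
}

#' Tree depth (maximum root-to-tip path length)
#' @param tree A `"phylo"` object.
#' @return Depth in the tree's branch-length units (Myr).
#' @export
tree_depth <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' Decompose a phylogeny into branch segments
#'
#' Each edge of the tree becomes one segment holding its length `L_i` and the
#' set of tip labels descending from it. This is the decomposition over which
#' phylogenetic Hill diversity is computed: each branch is weighted by the
#' summed relative abundance of its descendant tips.
#'
#' @param tree A `"phylo"` object.
#' @return A data frame with columns `length` (numeric) and `descendants`
#'   (list of character vectors), one row per edge. Satisfies the
#'   conservation identity `sum(length * lengths(descendants))` = total
#'   root-to-tip path length summed over tips.
#' @export
branch_segments <- function(tree) {
  ntip <- ape::Ntip(tree)
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  tr <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    tips_below[[par]] <- c(tips_below[[par]], tips_below[[child]])
  }
  data.frame(
    length = tree$edge.length,
    descendants = I(tips_below[tree$edge[, 2]])
  )
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the root-to-MRCA shared path length of tips i and j; the
#' diagonal holds root-to-tip depths (equal to tree depth when ultrametric).
#' This is the matrix that structures the phylogenetically correlated host
#' random effect; the model code divides by tree depth to obtain a
#' correlation matrix so the effect's scale parameter stays identifiable.
#'
#' @param tree An ultrametric `"phylo"` object.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
to_vcv <- function(tree) {
  tree <- validate_tree(tree, ultrametric = TRUE)
  v <- ape::vcv(tree)
  # ape returns tips in tree order already; enforce symmetry against fp noise
  (v + t(v)) / 2
}

#' Depth-normalized phylogenetic correlation matrix
#' @inheritParams to_vcv
#' @return `to_vcv(tree)` divided by tree depth (unit diagonal).
#' @export
phylo_correlation <- function(tree) {
  v <- to_vcv(tree)
  v / mean(diag(v))
}

#' Star phylogeny
#'
#' All tips attach directly to the root with equal branch length. Used as the
#' relatedness-free reference: phylogenetic Hill diversity on a star tree
#' equals the ordinary (taxonomic) Hill number.
#'
#' @param tips Character vector of tip labels (at least one).
#' @param depth Branch length from root to every tip (default 1).
#' @return A `"phylo"` object.
#' @export
star_tree <- function(tips, depth = 1) {
  if (length(tips) < 1L) stop("star_tree needs at least one tip", call. = FALSE)
  tips <- trimws(tips)
  if (length(tips) == 1L) {
    # single-tip "tree": build by hand, ape cannot parse one-tip newick
    tr <- structure(list(
      edge = matrix(c(2L, 1L), 1, 2),
      edge.length = depth,
      tip.label = tips,
      Nnode = 1L
    ), class = "phylo", order = "cladewise")
    return(tr)
  }
  parse_newick(paste0("(", paste0(tips, ":", format(depth, digits = 15),
                                  collapse = ","), ");"))
}

#' Patristic distance matrix
#' @param tree A `"phylo"` object.
#' @return Matrix of pairwise tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree) {
  ape::cophenetic.phylo(tree)
}

#' A synthetic seven-host time tree
#'
#' A fully synthetic ultrametric phylogeny for seven host species whose
#' deepest split is 47 Myr, matching the depth scale of the drosophilid host
#' clade the experimental design emulates. The topology and node ages are
#' invented for testing and examples; they are not estimates for any real
#' species.
#'
#' @param tips Optional character vector of 7 labels (default `H1..H7`).
#' @return A `"phylo"` object with 7 tips and depth 47.
#' @export
example_host_tree <- function(tips = paste0("H", 1:7)) {
  stopifnot(length(tips) == 7L)
  nwk <- "(((T1:10,T2:10):15,(T3:20,T4:20):5):22,((T5:30,T6:30):10,T7:40):7);"
  tr <- parse_newick(nwk)
  tr$tip.label <- tips[match(tr$tip.label, paste0("T", 1:7))]
  tr
}

#' Check that a tree covers a set of taxa
#'
#' Exact-string matching after whitespace trimming; a mismatch is a hard
#' error, never a silent drop.
#' @param tree A `"phylo"` object.
#' @param taxa Character vector of required labels.
#' @keywords internal
check_tree_covers <- function(tree, taxa) {
  missing <- setdiff(trimws(taxa), trimws(tree$tip.label))
  if (length(missing)) {
    stop("tree does not cover taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}
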