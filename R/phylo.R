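#' Read and validate an ultrametric newick tree
#'
#' Parses a newick string or file into an `ape::phylo` tree and (by default)
#' checks ultrametricity: all root-to-leaf path lengths equal within a
#' relative tolerance. Non-ultrametric trees are rejected unless
#' `height_normalize = TRUE`, which stretches each terminal branch so every
#' leaf sits at the maximum depth.
#'
#' @param text A newick string (with branch lengths and a terminating `;`).
#' @param file Alternatively, a path to a newick file.
#' @param validate_ultrametric Check ultrametricity? Default `TRUE`.
#' @param tol Relative tolerance on root-to-leaf depth spread. Default 1e-6.
#' @param height_normalize Rescale terminal branches so all leaf depths equal
#'   the tree height instead of rejecting. Default `FALSE`.
#' @return An `ape::phylo` tree.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' @export
read_newick <- function(text = NULL, file = NULL, validate_ultrametric = TRUE,
                        tol = 1e-6, height_normalize = FALSE) {
  if (is.null(text) == is.null(file)) {
    abort("supply exactly one of `text` or `file`.", class = "relaxsel_invalid_input")
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_syntax(text)
  tree <- tryCatch(
    withCallingHandlers(
      ape::read.tree(text = text),
      warning = function(w) abort(paste0("newick parse error: ", conditionMessage(w)),
                                  class = "relaxsel_parse_error")
    ),
    error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)),
                              class = "relaxsel_parse_error")
  )
  if (is.null(tree)) abort("newick parse error.", class = "relaxsel_parse_error")
  if (anyDuplicated(tree$tip.label)) {
    abort("leaf labels must be unique.", class = "relaxsel_invalid_input")
  }
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    abort("tree must have non-negative branch lengths.",
          class = "relaxsel_invalid_input")
  }
  if (height_normalize) tree <- normalize_leaf_depths(tree)
  if (validate_ultrametric && !is_ultrametric_tol(tree, tol)) {
    abort(paste0("tree is not ultrametric within relative tolerance ", tol,
                 "; set height_normalize = TRUE to rescale terminal branches."),
          class = "relaxsel_not_ultrametric")
  }
  tree
}

# Cheap structural scan so parse failures report a character position,
# which ape::read.tree does not.
check_newick_syntax <- function(text) {
  if (!nzchar(trimws(text))) {
    abort("newick parse error: empty string.", class = "relaxsel_parse_error")
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("newick parse error: unmatched ')' at position %d.", i),
              class = "relaxsel_parse_error")
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf("newick parse error: %d unclosed '(' at end of string.", depth),
          class = "relaxsel_parse_error")
  }
  if (!grepl(";\\s*$", text)) {
    abort(sprintf("newick parse error: missing terminating ';' (position %d).",
                  nchar(text) + 1L),
          class = "relaxsel_parse_error")
  }
  invisible(TRUE)
}

leaf_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}

is_ultrametric_tol <- function(tree, tol = 1e-6) {
  d <- leaf_depths(tree)
  h <- max(d)
  h > 0 && (h - min(d)) / h <= tol
}

normalize_leaf_depths <- function(tree) {
  d <- leaf_depths(tree)
  h <- max(d)
  term <- match(seq_along(tree$tip.label), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (h - d)
  tree
}

#' Prune a tree to a set of species
#'
#' Keeps exactly the requested leaves; path lengths between kept leaves are
#' unchanged and degree-2 internal nodes are collapsed with branch lengths
#' summed.
#'
#' @param tree An `ape::phylo` tree.
#' @param keep Character vector of leaf labels to retain.
#' @return The pruned `ape::phylo` tree.
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    abort(paste0("species not in tree: ", paste(missing, collapse = ", ")),
          class = "relaxsel_missing_species")
  }
  if (length(keep) == length(tree$tip.label)) return(tree)
  if (length(keep) == 1) {
    # single-leaf tree: ape's pruning does not support it directly
    d <- leaf_depths(tree)[match(keep, tree$tip.label)]
    return(ape::read.tree(text = sprintf("(%s:%.10g);", keep, d)))
  }
  ape::keep.tip(tree, keep)
}

#' Resolve requested species against tree leaves via congener substitutions
#'
#' Species absent from the phylogeny may be represented by a closely related
#' (congeneric) species supplied in `mapping`. Every requested species must
#' resolve to a leaf; substitutions are reported in the result.
#'
#' @param requested Character vector of species ids needed by the analysis.
#' @param tree_labels Character vector of available leaf labels.
#' @param mapping Named character vector `c(requested = substitute, ...)`
#'   (may be `NULL`).
#' @return A tibble with columns `requested`, `resolved`, `substituted`.
#' @export
substitute_congeners <- function(requested, tree_labels, mapping = NULL) {
  requested <- as.character(requested)
  resolved <- requested
  subbed <- rep(FALSE, length(requested))
  absent <- !requested %in% tree_labels
  if (any(absent)) {
    mapped <- requested[absent] %in% names(mapping)
    resolved[absent][mapped] <- unname(mapping[requested[absent][mapped]])
    subbed[absent][mapped] <- TRUE
    still <- resolved[absent][!mapped]
    bad_target <- resolved[absent][mapped][!resolved[absent][mapped] %in% tree_labels]
    still <- c(still, bad_target)
    if (length(still)) {
      abort(paste0("species missing from tree with no usable congener mapping: ",
                   paste(unique(still), collapse = ", ")),
            class = "relaxsel_missing_species")
    }
  }
  tibble::tibble(requested = requested, resolved = resolved, substituted = subbed)
}

#' Brownian-motion species correlation matrix from an ultrametric tree
#'
#' Under Brownian trait evolution the expected correlation between two
#' species is the depth of their most recent common ancestor divided by the
#' tree height. The result is symmetric, positive semi-definite, with unit
#' diagonal, ordered as the tree's tip labels; it is the relatedness
#' structure used by the phylogenetic random effect of the meta-regression.
#'
#' @param tree An ultrametric `ape::phylo` tree.
#' @param tol Ultrametricity tolerance passed to validation.
#' @return A correlation matrix with species ids as dimnames.
#' @examples
#' phylo_correlation(read_newick("((A:1,B:1):1,C:2);"))
#' @export
phylo_correlation <- function(tree, tol = 1e-6) {
  if (length(tree$tip.label) == 1) {
    return(matrix(1, 1, 1, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  if (max(leaf_depths(tree)) <= 0) {
    abort("tree height is zero; correlation undefined.",
          class = "relaxsel_invalid_input")
  }
  if (!is_ultrametric_tol(tree, tol)) {
    abort("tree is not ultrametric; cannot form a Brownian correlation matrix.",
          class = "relaxsel_not_ultrametric")
  }
  A <- ape::vcv(tree, corr = TRUE)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}
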