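#' Read an ASV phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants UniFrac
#' needs: unique leaf labels and non-negative branch lengths. A tree without
#' branch lengths gets unit lengths everywhere, with a warning, since
#' abundance-weighted UniFrac is undefined without them.
#'
#' @param path Newick file.
#' @param asv_ids Optional character vector; leaf labels not found in it are
#'   reported in a warning (they are harmless until a sample actually carries
#'   reads for a missing taxon).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path, asv_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("failed to parse Newick file '",
                                            path, "': ", conditionMessage(e),
                                            call. = FALSE))
  if (is.null(tree)) stop("failed to parse Newick file: ", path, call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all lengths to 1.0")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch length(s)", call. = FALSE)
  }
  if (!is.null(asv_ids)) {
    extra <- setdiff(tree$tip.label, asv_ids)
    if (length(extra) > 0L) {
      warning(length(extra), " tree leaf label(s) match no known ASV id, e.g. ",
              paste(utils::head(extra, 5L), collapse = ", "))
    }
  }
  tree
}

#' Write a phylogeny to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
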