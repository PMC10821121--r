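# Weighted UniFrac: a phylogeny-aware community distance. Every branch of the
# ASV tree is weighted by its length times the difference in the fraction of
# each community's reads that descend from it. The normalised form divides by
# sum_b l_b (p_b(x) + p_b(y)), bounding the distance in [0, 1].

#' Weighted UniFrac distance between two samples
#'
#' Both count vectors are rescaled to relative abundance internally, so the
#' result is invariant to sequencing depth. With `p_b(s)` the fraction of
#' sample `s` reads descending from branch `b` and `l_b` its length:
#' `raw = sum_b l_b |p_b(x) - p_b(y)|`, and the normalised distance divides by
#' `sum_b l_b (p_b(x) + p_b(y))`.
#'
#' @param x,y Named numeric vectors of counts (or abundances); names are ASV
#'   ids. Every taxon with a positive count must be a leaf of `tree`.
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param normalized If `TRUE` (default) return the normalised distance in
#'   `[0, 1]`; otherwise the raw branch-length-weighted sum.
#' @return The distance.
#' @seealso [unifrac_similarity()]
#' @export
weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  px <- .tip_proportions(x, tree)
  py <- .tip_proportions(y, tree)

  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  wx <- c(px, numeric(n_node))
  wy <- c(py, numeric(n_node))

  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  len <- post$edge.length
  # postorder guarantees children are accumulated before their parent
  for (k in seq_len(nrow(edge))) {
    wx[edge[k, 1L]] <- wx[edge[k, 1L]] + wx[edge[k, 2L]]
    wy[edge[k, 1L]] <- wy[edge[k, 1L]] + wy[edge[k, 2L]]
  }
  bx <- wx[edge[, 2L]]
  by <- wy[edge[, 2L]]
  raw <- sum(len * abs(bx - by))
  if (!normalized) return(raw)
  denom <- sum(len * (bx + by))
  if (denom == 0) return(0)
  raw / denom
}

#' Weighted UniFrac similarity
#'
#' Defined as `1 -` the normalised weighted UniFrac distance; used to measure
#' donor-recipient microbiome overlap before FMT.
#'
#' @inheritParams weighted_unifrac
#' @return Similarity in `[0, 1]`.
#' @export
unifrac_similarity <- function(x, y, tree) {
  1 - weighted_unifrac(x, y, tree, normalized = TRUE)
}

# Map a named count vector onto the tree tips as relative abundances.
.tip_proportions <- function(x, tree) {
  if (is.null(names(x))) {
    stop("count vectors must be named by ASV id for UniFrac", call. = FALSE)
  }
  present <- names(x)[x > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing) > 0L) {
    stop("taxa with reads absent from the tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  total <- sum(x)
  if (total <= 0) stop("sample has zero total abundance", call. = FALSE)
  p <- numeric(length(tree$tip.label))
  idx <- match(present, tree$tip.label)
  p[idx] <- x[present] / total
  p
}
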