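# Pairwise community dissimilarities. Each metric is implemented from its
# definition; distance_matrix() applies one metric across all sample pairs of
# a count table.

#' Jaccard distance between presence sets
#'
#' `1 - |a intersect b| / |a union b|` on ASV presence/absence. Two empty
#' communities are defined to be at distance 0 (logged via a message).
#'
#' @param a,b Character vectors of ASV ids present in each sample.
#' @return Distance in `[0, 1]`.
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0L) {
    message("jaccard_distance: both presence sets empty; returning 0 by convention")
    return(0)
  }
  1 - length(intersect(a, b)) / length(u)
}

#' Bray-Curtis dissimilarity on proportions
#'
#' `sum |x_i - y_i| / sum (x_i + y_i)`; for vectors normalised to 1 this is
#' `sum |x_i - y_i| / 2`.
#'
#' @param x,y Aligned abundance vectors (same taxa, same order; if named, the
#'   names must match).
#' @return Distance in `[0, 1]` for non-negative inputs.
#' @export
bray_curtis <- function(x, y) {
  .check_aligned(x, y)
  denom <- sum(x + y)
  if (denom == 0) return(0)
  sum(abs(x - y)) / denom
}

#' Aitchison distance between CLR vectors
#'
#' Euclidean distance in CLR space (see [clr_transform()]); both vectors must
#' come from the same taxon alignment and pseudocount.
#'
#' @param x,y Aligned CLR-transformed vectors.
#' @return Non-negative distance.
#' @export
aitchison_distance <- function(x, y) {
  .check_aligned(x, y)
  sqrt(sum((x - y)^2))
}

#' All-pairs distance matrix for a count table
#'
#' @param counts ASV count matrix (samples x ASVs).
#' @param metric One of `"jaccard"`, `"bray_curtis"`, `"aitchison"`,
#'   `"unifrac"`.
#' @param tree [ape::phylo] tree over the ASVs; required for
#'   `metric = "unifrac"`.
#' @param pseudocount CLR pseudocount for `metric = "aitchison"`.
#' @return Square symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
distance_matrix <- function(counts,
                            metric = c("jaccard", "bray_curtis", "aitchison",
                                       "unifrac"),
                            tree = NULL, pseudocount = 0.5) {
  metric <- match.arg(metric)
  counts <- validate_asv_table(counts)
  n <- nrow(counts)
  ids <- rownames(counts)

  pairfun <- switch(metric,
    jaccard = {
      sets <- lapply(ids, function(s) colnames(counts)[counts[s, ] > 0])
      function(i, j) jaccard_distance(sets[[i]], sets[[j]])
    },
    bray_curtis = {
      props <- to_proportions(counts)
      function(i, j) bray_curtis(props[i, ], props[j, ])
    },
    aitchison = {
      clr <- clr_transform(counts, pseudocount)
      function(i, j) aitchison_distance(clr[i, ], clr[j, ])
    },
    unifrac = {
      if (is.null(tree)) {
        stop("metric = 'unifrac' requires a tree", call. = FALSE)
      }
      function(i, j) weighted_unifrac(counts[i, ], counts[j, ], tree)
    })

  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d[i, j] <- d[j, i] <- pairfun(i, j)
      }
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Write a distance matrix to TSV
#'
#' @param d Square distance matrix with sample ids as dimnames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  metric <- attr(d, "metric")
  writeLines(paste0("# fmtengraft ", .pkg_version(), " distance matrix",
                    if (!is.null(metric)) paste0(" (", metric, ")")), con)
  writeLines(paste(c("sample_id", colnames(d)), collapse = "\t"), con)
  body <- apply(d, 1L, function(r) paste(format(r, digits = 15, trim = TRUE),
                                         collapse = "\t"))
  writeLines(paste(rownames(d), body, sep = "\t"), con)
  invisible(path)
}

.check_aligned <- function(x, y) {
  if (length(x) != length(y)) {
    stop("vectors have different lengths (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (!is.null(names(x)) && !is.null(names(y)) && !identical(names(x), names(y))) {
    stop("vectors are not aligned to the same taxa", call. = FALSE)
  }
  invisible(TRUE)
}
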