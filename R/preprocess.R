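# Filtering and normalisation applied ahead of the engraftment and diversity
# analyses. The rare-ASV filter and rarefaction serve different branches of
# the pipeline: the filter precedes presence/absence engraftment calls (a
# one- or two-read ASV can fabricate a shared taxon), rarefaction precedes
# alpha diversity (richness estimates scale with depth). They are never
# chained by default.

#' Remove dataset-wide rare ASVs (singletons/doubletons)
#'
#' Drops every ASV whose summed count across *all* samples is at most
#' `max_total` (default 2, i.e. singletons and doubletons). Such ASVs are
#' overwhelmingly sequencing artefacts and would otherwise inflate
#' presence/absence engraftment calls.
#'
#' @param counts Validated ASV count matrix (samples x ASVs).
#' @param max_total ASVs with total count `<= max_total` are removed.
#' @return A list: `counts` (filtered matrix, same samples) and `report`
#'   (list with `n_asvs_before`, `n_asvs_removed`, `removed_ids`).
#' @export
remove_rare_asvs <- function(counts, max_total = 2) {
  counts <- validate_asv_table(counts)
  totals <- colSums(counts)
  drop <- totals <= max_total
  removed <- colnames(counts)[drop]
  kept <- counts[, !drop, drop = FALSE]
  if (ncol(kept) == 0L) {
    warning("rare-ASV filter removed every ASV (max_total = ", max_total, ")")
  }
  list(counts = kept,
       report = list(n_asvs_before = ncol(counts),
                     n_asvs_removed = length(removed),
                     removed_ids = removed))
}

#' Rarefy samples to a common sequencing depth
#'
#' Subsamples each sample's reads to exactly `depth` without replacement (a
#' multivariate hypergeometric draw). Samples with fewer than `depth` reads
#' are excluded, not up-sampled. Deterministic for a given `seed`; the caller
#' RNG state is left untouched.
#'
#' @param counts Validated ASV count matrix.
#' @param depth Target depth in reads (default 26000).
#' @param seed Integer seed; required so that rarefied analyses are
#'   reproducible.
#' @return A list: `counts` (rarefied matrix, excluded samples dropped),
#'   `depth`, `seed`, `excluded_samples` (character vector).
#' @export
rarefy <- function(counts, depth = 26000, seed) {
  if (missing(seed)) stop("rarefy() requires an explicit seed", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  counts <- validate_asv_table(counts)
  totals <- rowSums(counts)
  excluded <- rownames(counts)[totals < depth]
  keep <- counts[totals >= depth, , drop = FALSE]
  out <- with_seed(seed, {
    t(apply(keep, 1L, function(row) {
      reads <- rep.int(seq_along(row), row)
      tabulate(sample(reads, depth), nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(keep)
  list(counts = out, depth = depth, seed = seed,
       excluded_samples = excluded)
}

#' Convert counts to within-sample proportions
#'
#' @param counts Validated ASV count matrix; every sample must have at least
#'   one read.
#' @return Matrix of relative abundances; each row sums to 1.
#' @export
to_proportions <- function(counts) {
  counts <- validate_asv_table(counts)
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(rownames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 1L, totals, "/")
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, `clr(x_i) = ln(x_i + pc) - mean_j ln(x_j + pc)`, the transform
#' underlying Aitchison distances on compositional count data. A pseudocount
#' keeps zero counts finite.
#'
#' @param counts ASV count matrix (samples x ASVs).
#' @param pseudocount Positive offset added to every count (default 0.5).
#' @return Matrix of CLR values; each row sums to 0.
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  m <- log(as.matrix(counts) + pseudocount)
  sweep(m, 1L, rowMeans(m), "-")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
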