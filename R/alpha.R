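# Alpha-diversity estimators, implemented directly from their defining
# formulas. Shannon is in natural log units (nats); Gini-Simpson is
# 1 - Simpson's concentration, i.e. the probability that two random reads
# belong to different taxa.

#' Chao1 richness estimator
#'
#' Classic abundance-based Chao1: with `S` observed taxa, `F1` singletons and
#' `F2` doubletons, returns `S + F1^2 / (2 F2)` when `F2 > 0` and the
#' `S + F1 (F1 - 1) / 2` fallback when `F2 = 0`. The bias-corrected variant
#' `S + F1 (F1 - 1) / (2 (F2 + 1))` is available behind a flag.
#'
#' @param counts Non-negative integer vector of per-taxon read counts.
#' @param bias_corrected Use the bias-corrected form.
#' @return Estimated richness; 0 for an all-zero vector.
#' @export
chao1 <- function(counts, bias_corrected = FALSE) {
  counts <- .check_count_vector(counts)
  s_obs <- sum(counts > 0)
  if (s_obs == 0L) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) return(s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Shannon diversity (nats)
#'
#' `H = -sum p_i ln p_i` over taxa with positive abundance.
#'
#' @param counts Non-negative vector of counts or abundances with positive sum.
#' @return Shannon entropy in nats.
#' @export
shannon_index <- function(counts) {
  p <- .to_probs(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson evenness
#'
#' `1 - sum p_i^2`, the complement of Simpson's concentration index.
#'
#' @param counts Non-negative vector of counts or abundances with positive sum.
#' @return Value in `[0, 1)`.
#' @export
gini_simpson <- function(counts) {
  p <- .to_probs(counts)
  1 - sum(p^2)
}

#' Per-sample alpha-diversity table
#'
#' Computes Chao1 richness, Shannon diversity and Gini-Simpson evenness for
#' every sample. For depth-controlled estimates, rarefy first (see [rarefy()]).
#'
#' @param counts ASV count matrix (samples x ASVs).
#' @return data.frame with columns `sample_id`, `chao1`, `shannon`,
#'   `gini_simpson`.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_asv_table(counts)
  data.frame(
    sample_id = rownames(counts),
    chao1 = apply(counts, 1L, chao1),
    shannon = apply(counts, 1L, shannon_index),
    gini_simpson = apply(counts, 1L, gini_simpson),
    row.names = NULL, stringsAsFactors = FALSE)
}

.check_count_vector <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  round(counts)
}

.to_probs <- function(counts) {
  if (any(counts < 0) || any(is.na(counts))) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("total abundance must be positive", call. = FALSE)
  counts / total
}
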