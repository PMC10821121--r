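# Independent brute-force oracles used to validate the implementations.
# Deliberately written with different mechanisms than the package code
# (direct formula transcription, recursive set enumeration, pairwise
# comparison counting).

bf_chao1 <- function(x) {
  s <- sum(x > 0)
  if (s == 0) return(0)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  if (f2 > 0) s + f1 * f1 / (2 * f2) else s + f1 * (f1 - 1) / 2
}

bf_shannon <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

bf_gini_simpson <- function(x) {
  p <- x / sum(x)
  1 - sum(p * p)
}

bf_jaccard <- function(a, b) {
  u <- unique(c(a, b))
  if (length(u) == 0) return(0)
  shared <- sum(vapply(u, function(t) t %in% a && t %in% b, logical(1)))
  1 - shared / length(u)
}

bf_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)

bf_aitchison <- function(x, y) sqrt(sum((x - y)^2))

# Weighted UniFrac by explicit enumeration of every branch's descendant
# leaf set (recursive), independent of the package's postorder accumulation.
bf_weighted_unifrac <- function(x, y, tree, normalized = TRUE) {
  tips <- tree$tip.label
  px <- setNames(numeric(length(tips)), tips)
  py <- px
  px[names(x)[x > 0]] <- x[x > 0] / sum(x)
  py[names(y)[y > 0]] <- y[y > 0] / sum(y)
  descendant_tips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, descendant_tips))
  }
  raw <- 0; denom <- 0
  for (k in seq_len(nrow(tree$edge))) {
    set <- descendant_tips(tree$edge[k, 2])
    pa <- sum(px[set]); pb <- sum(py[set])
    raw <- raw + tree$edge.length[k] * abs(pa - pb)
    denom <- denom + tree$edge.length[k] * (pa + pb)
  }
  if (!normalized) return(raw)
  if (denom == 0) return(0)
  raw / denom
}

# Engraftment by exhaustive per-ASV membership enumeration.
bf_engraftment <- function(counts, donor, pre, post) {
  eligible <- character(); engrafted <- character()
  for (a in colnames(counts)) {
    in_d <- counts[donor, a] >= 1
    in_p <- counts[pre, a] >= 1
    in_q <- counts[post, a] >= 1
    if (in_d && !in_p) {
      eligible <- c(eligible, a)
      if (in_q) engrafted <- c(engrafted, a)
    }
  }
  list(eligible = eligible, engrafted = engrafted,
       rate = if (length(eligible) > 0)
         100 * length(engrafted) / length(eligible) else NA_real_)
}

# Mann-Whitney U by counting pairwise wins (ties count 1/2).
bf_mann_whitney_u <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  u
}

# Random small count table fixture.
random_counts <- function(n_samples, n_asvs, lambda = 5) {
  m <- matrix(stats::rpois(n_samples * n_asvs, lambda),
              nrow = n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("asv", seq_len(n_asvs))))
  m
}
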