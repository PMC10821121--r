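# Engraftment core. For each donor/pre/post triad with presence sets D, P, Q
# (taken after the dataset-wide rare-ASV filter):
#
#   eligible  = D \ P                 donor ASVs with the capacity to engraft
#   engrafted = (Q intersect D) \ P   those actually observed post-FMT
#   rate      = 100 |engrafted| / |eligible|
#
# and every post-FMT ASV is attributed to one of four sources:
# always-shared (D intersect P), donor-derived (D \ P), recipient-derived
# (P \ D), or environmental/stochastic (none of the above).

#' ASV presence set of a sample
#'
#' @param counts ASV count matrix (apply [remove_rare_asvs()] first for
#'   engraftment analyses).
#' @param sample_id Sample to query.
#' @param min_presence Minimum count for an ASV to be called present
#'   (default 1 read).
#' @return Character vector of ASV ids.
#' @export
presence_set <- function(counts, sample_id, min_presence = 1) {
  if (!sample_id %in% rownames(counts)) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  out <- colnames(counts)[counts[sample_id, ] >= min_presence]
  if (length(out) == 0L) {
    warning("sample '", sample_id, "' has an empty presence set")
  }
  out
}

#' Donor-ASV engraftment rate for one triad
#'
#' The percentage of the donor's ASVs *not already present in the recipient
#' pre-FMT* that are found in the recipient post-FMT. A triad whose eligible
#' set is empty (donor entirely contained in the pre-FMT community) has an
#' undefined rate and is flagged `defined = FALSE`.
#'
#' @param triad One row of the triads data.frame from [assemble_triads()]
#'   (or any list with `recipient_id`, `donor_sample`, `pre_sample`,
#'   `post_sample`).
#' @param counts ASV count matrix, rare-ASV-filtered.
#' @param min_presence Presence threshold in reads.
#' @return An object of class `engraftment_result`: list with `recipient_id`,
#'   `donor_set_size`, `eligible_set`, `engrafted_set`, `n_eligible`,
#'   `n_engrafted`, `rate_percent`, `defined`.
#' @export
engraftment_rate <- function(triad, counts, min_presence = 1) {
  D <- presence_set(counts, triad$donor_sample, min_presence)
  P <- presence_set(counts, triad$pre_sample, min_presence)
  Q <- presence_set(counts, triad$post_sample, min_presence)
  eligible <- setdiff(D, P)
  engrafted <- setdiff(intersect(Q, D), P)
  defined <- length(eligible) > 0L
  structure(list(
    recipient_id = triad$recipient_id,
    donor_set_size = length(D),
    eligible_set = eligible,
    engrafted_set = engrafted,
    n_eligible = length(eligible),
    n_engrafted = length(engrafted),
    rate_percent = if (defined) 100 * length(engrafted) / length(eligible)
                   else NA_real_,
    defined = defined), class = "engraftment_result")
}

#' @export
print.engraftment_result <- function(x, ...) {
  cat("Engraftment result for recipient '", x$recipient_id, "'\n", sep = "")
  cat("  donor ASVs:", x$donor_set_size,
      "| eligible:", x$n_eligible,
      "| engrafted:", x$n_engrafted, "\n")
  if (x$defined) {
    cat(sprintf("  engraftment rate: %.2f%%\n", x$rate_percent))
  } else {
    cat("  engraftment rate: undefined (empty eligible set)\n")
  }
  invisible(x)
}

#' Classify ASV provenance at a stage
#'
#' Labels every ASV present in the recipient at `stage` by its source:
#' `always_shared` (donor and recipient pre-FMT), `donor_derived` (donor
#' only), `recipient_derived` (recipient pre-FMT only) or `environmental`
#' (neither). At the pre-FMT stage only `always_shared` and
#' `recipient_derived` can occur, by construction.
#'
#' @inheritParams engraftment_rate
#' @param stage `"preFMT"` or `"postFMT"`.
#' @return Named character vector: ASV id -> class.
#' @export
classify_provenance <- function(triad, counts, stage = c("postFMT", "preFMT"),
                                min_presence = 1) {
  stage <- match.arg(stage)
  D <- presence_set(counts, triad$donor_sample, min_presence)
  P <- presence_set(counts, triad$pre_sample, min_presence)
  S <- if (stage == "preFMT") P else
    presence_set(counts, triad$post_sample, min_presence)
  cls <- ifelse(S %in% D & S %in% P, "always_shared",
         ifelse(S %in% D, "donor_derived",
         ifelse(S %in% P, "recipient_derived", "environmental")))
  stats::setNames(cls, S)
}

#' Abundance fractions of the four provenance classes
#'
#' The share of the stage sample's total reads contributed by each provenance
#' class; the four fractions always sum to 1 (pre-FMT samples can only have
#' `always_shared` and `recipient_derived` mass).
#'
#' @inheritParams classify_provenance
#' @return data.frame row: `recipient_id`, `stage`, `fraction_always_shared`,
#'   `fraction_donor_derived`, `fraction_recipient_derived`,
#'   `fraction_environmental`.
#' @export
provenance_fractions <- function(triad, counts,
                                 stage = c("postFMT", "preFMT"),
                                 min_presence = 1) {
  stage <- match.arg(stage)
  cls <- classify_provenance(triad, counts, stage, min_presence)
  sample_id <- if (stage == "preFMT") triad$pre_sample else triad$post_sample
  row <- counts[sample_id, names(cls)]
  total <- sum(counts[sample_id, ])
  if (total == 0) {
    stop("sample '", sample_id, "' has zero total count", call. = FALSE)
  }
  frac <- function(class) sum(row[cls == class]) / total
  data.frame(
    recipient_id = triad$recipient_id,
    stage = stage,
    fraction_always_shared = frac("always_shared"),
    fraction_donor_derived = frac("donor_derived"),
    fraction_recipient_derived = frac("recipient_derived"),
    fraction_environmental = frac("environmental"),
    stringsAsFactors = FALSE)
}

#' Taxon-level engraftment frequencies
#'
#' Each (triad, engrafted ASV) pair is one engraftment event. Events are
#' grouped by the ASV's lowest classified taxon label (see [taxon_label()])
#' and reported as counts and percentages of all events, sorted descending.
#'
#' @param results List of [engraftment_rate()] results.
#' @param taxonomy Taxonomy data.frame from [read_taxonomy()].
#' @return data.frame: `taxon`, `n_engraftment_events`,
#'   `percent_of_all_events` (sums to 100).
#' @export
taxon_engraftment_frequency <- function(results, taxonomy) {
  engrafted <- unlist(lapply(results, `[[`, "engrafted_set"))
  if (length(engrafted) == 0L) {
    return(data.frame(taxon = character(), n_engraftment_events = integer(),
                      percent_of_all_events = numeric(),
                      stringsAsFactors = FALSE))
  }
  labels <- taxon_label(engrafted, taxonomy)
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(
    taxon = names(tab),
    n_engraftment_events = as.integer(tab),
    percent_of_all_events = 100 * as.numeric(tab) / length(engrafted),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Lowest classified taxon label of ASVs
#'
#' Returns the deepest rank (domain through genus) that carries a real
#' classification. When the genus itself is unclassified the label is the
#' deepest classified rank prefixed `"unclassified "` (e.g. an ASV known only
#' to family Ruminococcaceae becomes `"unclassified Ruminococcaceae"`); labels
#' already marked uncultured/unclassified are kept verbatim.
#'
#' @param asv_ids Character vector of ASV ids.
#' @param taxonomy Taxonomy data.frame from [read_taxonomy()].
#' @return Character vector of labels, one per input ASV.
#' @export
taxon_label <- function(asv_ids, taxonomy) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  idx <- match(asv_ids, taxonomy$asv_id)
  if (anyNA(idx)) {
    stop("ASV(s) missing from taxonomy: ",
         paste(asv_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  vapply(idx, function(i) {
    vals <- as.character(taxonomy[i, ranks])
    known <- !grepl("^unclassified", vals, ignore.case = TRUE) & nzchar(vals)
    if (!any(known)) return("unclassified")
    deepest <- max(which(known))
    v <- vals[deepest]
    if (deepest < length(ranks) &&
        !grepl("^(unclassified|uncultured)", v, ignore.case = TRUE)) {
      paste("unclassified", v)
    } else {
      v
    }
  }, character(1))
}
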