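#' Fit the donor-engraftment analysis to an FMT cohort
#'
#' The package's central estimator. Filters dataset-wide rare ASVs, assembles
#' donor / pre-FMT / post-FMT triads, computes each recipient's donor-ASV
#' engraftment rate, partitions pre- and post-FMT microbiomes into the four
#' provenance classes (always-shared, donor-derived, recipient-derived,
#' environmental), tallies which taxa engraft most often, and relates
#' donor-recipient community overlap before FMT to the donor-derived
#' abundance after FMT via a Spearman correlation.
#'
#' @param x ASV count matrix (samples x ASVs), or an `fmt_cohort` from
#'   [simulate_cohort()].
#' @param ... Passed to methods.
#' @return An object of class `fmt_engraftment`; see
#'   [fmt_engraftment.default()] for its contents and the available methods
#'   (`print`, `summary`, `coef`, `plot`, `simulate`).
#' @examples
#' cohort <- simulate_cohort(n_triads = 8, n_donors = 2, seed = 42)
#' fit <- fmt_engraftment(cohort)
#' fit
#' coef(fit)
#' @export
fmt_engraftment <- function(x, ...) UseMethod("fmt_engraftment")

#' @rdname fmt_engraftment
#' @export
fmt_engraftment.fmt_cohort <- function(x, ...) {
  fmt_engraftment(x$counts, metadata = x$metadata, taxonomy = x$taxonomy,
                  tree = x$tree, ...)
}

#' @rdname fmt_engraftment
#' @param metadata Sample metadata data.frame (see [read_metadata()]).
#' @param taxonomy Optional taxonomy data.frame (see [read_taxonomy()]);
#'   enables the engrafted-taxa summary.
#' @param tree Optional [ape::phylo] tree over the ASVs; when present,
#'   donor-recipient overlap is weighted UniFrac similarity, otherwise
#'   Bray-Curtis similarity on proportions.
#' @param donor_policy How to resolve donors with multiple samples
#'   (see [assemble_triads()]).
#' @param min_presence Reads required to call an ASV present.
#' @param rare_max_total Dataset-wide total count at or below which an ASV is
#'   discarded before analysis (default 2: singletons and doubletons).
#' @export
fmt_engraftment.default <- function(x, metadata, taxonomy = NULL, tree = NULL,
                                    donor_policy = "single",
                                    min_presence = 1, rare_max_total = 2,
                                    ...) {
  filt <- remove_rare_asvs(validate_asv_table(x), max_total = rare_max_total)
  asm <- assemble_triads(filt$counts, metadata, donor_policy)
  counts <- asm$counts
  triads <- asm$triads

  results <- lapply(seq_len(nrow(triads)), function(i) {
    engraftment_rate(triads[i, ], counts, min_presence)
  })
  names(results) <- triads$recipient_id

  partitions <- do.call(rbind, lapply(seq_len(nrow(triads)), function(i) {
    rbind(provenance_fractions(triads[i, ], counts, "preFMT", min_presence),
          provenance_fractions(triads[i, ], counts, "postFMT", min_presence))
  }))

  rates <- data.frame(
    recipient_id = triads$recipient_id,
    donor_id = triads$donor_id,
    donor_set_size = vapply(results, `[[`, integer(1), "donor_set_size"),
    n_eligible = vapply(results, `[[`, integer(1), "n_eligible"),
    n_engrafted = vapply(results, `[[`, integer(1), "n_engrafted"),
    rate_percent = vapply(results, `[[`, numeric(1), "rate_percent"),
    defined = vapply(results, `[[`, logical(1), "defined"),
    row.names = NULL, stringsAsFactors = FALSE)

  taxa <- if (!is.null(taxonomy)) {
    taxon_engraftment_frequency(results, taxonomy)
  }

  sim_metric <- if (!is.null(tree)) "unifrac" else "bray_curtis"
  similarity <- vapply(seq_len(nrow(triads)), function(i) {
    d <- counts[triads$donor_sample[i], ]
    p <- counts[triads$pre_sample[i], ]
    if (sim_metric == "unifrac") {
      unifrac_similarity(d, p, tree)
    } else {
      1 - bray_curtis(d / sum(d), p / sum(p))
    }
  }, numeric(1))
  post <- partitions[partitions$stage == "postFMT", , drop = FALSE]
  overlap <- data.frame(
    recipient_id = triads$recipient_id,
    similarity = similarity,
    donor_derived_fraction = post$fraction_donor_derived[
      match(triads$recipient_id, post$recipient_id)],
    row.names = NULL, stringsAsFactors = FALSE)
  correlation <- spearman_cor(overlap$similarity,
                              overlap$donor_derived_fraction)

  structure(list(
    triads = triads,
    results = results,
    rates = rates,
    partitions = partitions,
    taxa = taxa,
    overlap = overlap,
    similarity_metric = sim_metric,
    correlation = correlation,
    summary = summarize_cohort(results, partitions),
    filter_report = filt$report,
    n_asvs = ncol(counts),
    call = match.call()),
    class = "fmt_engraftment")
}

#' @export
print.fmt_engraftment <- function(x, ...) {
  cat("FMT donor-engraftment analysis\n")
  cat("  triads:", nrow(x$triads),
      "| ASVs after rare filter:", x$n_asvs,
      "(", x$filter_report$n_asvs_removed, "singleton/doubleton ASVs removed)\n")
  s <- x$summary$rates
  cat(sprintf("  engraftment rate: mean %.2f%%, median %.2f%%, range %.2f-%.2f%%\n",
              s$mean, s$median, s$min, s$max))
  if (x$correlation$defined) {
    cat(sprintf("  overlap (%s similarity) vs donor-derived fraction: rho = %.3f, p = %.3g\n",
                x$similarity_metric, x$correlation$rho, x$correlation$p_value))
  }
  invisible(x)
}

#' @export
summary.fmt_engraftment <- function(object, ...) {
  structure(list(cohort = object$summary,
                 correlation = object$correlation,
                 similarity_metric = object$similarity_metric,
                 taxa = object$taxa,
                 filter_report = object$filter_report,
                 n_triads = nrow(object$triads)),
            class = "summary.fmt_engraftment")
}

#' @export
print.summary.fmt_engraftment <- function(x, ...) {
  print(x$cohort)
  if (x$correlation$defined) {
    cat(sprintf("  donor-recipient overlap (%s) vs donor-derived abundance: rho = %.3f, p = %.3g, n = %d\n",
                x$similarity_metric, x$correlation$rho, x$correlation$p_value,
                x$correlation$n))
  }
  if (!is.null(x$taxa) && nrow(x$taxa) > 0L) {
    cat("  most frequently engrafted taxa:\n")
    top <- utils::head(x$taxa, 5L)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-35s %4d events (%.2f%%)\n", top$taxon[i],
                  top$n_engraftment_events[i], top$percent_of_all_events[i]))
    }
  }
  invisible(x)
}

#' @export
coef.fmt_engraftment <- function(object, ...) {
  s <- object$summary
  c(mean_rate_percent = s$rates$mean,
    median_rate_percent = s$rates$median,
    post_always_shared = unname(s$mean_fractions$postFMT["fraction_always_shared"]),
    post_donor_derived = unname(s$mean_fractions$postFMT["fraction_donor_derived"]),
    post_recipient_derived = unname(s$mean_fractions$postFMT["fraction_recipient_derived"]),
    post_environmental = unname(s$mean_fractions$postFMT["fraction_environmental"]),
    pre_always_shared = unname(s$mean_fractions$preFMT["fraction_always_shared"]),
    pre_recipient_derived = unname(s$mean_fractions$preFMT["fraction_recipient_derived"]),
    overlap_rho = object$correlation$rho)
}

#' @export
plot.fmt_engraftment <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4.5, 4, 3, 1))
  on.exit(graphics::par(op))
  r <- x$rates$rate_percent[x$rates$defined]
  graphics::hist(r, breaks = "FD", col = "grey80", border = "white",
                 main = "Donor-ASV engraftment rates",
                 xlab = "Engraftment rate (%)")
  graphics::abline(v = mean(r), lty = 2)

  classes <- c("fraction_always_shared", "fraction_donor_derived",
               "fraction_recipient_derived", "fraction_environmental")
  m <- rbind(pre = x$summary$mean_fractions$preFMT[classes],
             post = x$summary$mean_fractions$postFMT[classes])
  graphics::barplot(t(m) * 100, beside = FALSE,
                    col = c("#4477aa", "#ee6677", "#228833", "#ccbb44"),
                    main = "Mean provenance fractions",
                    ylab = "Share of microbiome (%)",
                    names.arg = c("pre-FMT", "post-FMT"))
  graphics::legend("topright", bty = "n", cex = 0.7,
                   fill = c("#4477aa", "#ee6677", "#228833", "#ccbb44"),
                   legend = c("always shared", "donor-derived",
                              "recipient-derived", "environmental"))
  invisible(x)
}

#' Simulate replicate cohorts from a fitted engraftment analysis
#'
#' Generates synthetic cohorts whose engraftment probability and size match
#' the fitted estimates (mean rate / 100 and the number of triads), useful
#' for parametric-bootstrap style checks of the pipeline.
#'
#' @param object A fitted `fmt_engraftment` object.
#' @param nsim Number of cohorts.
#' @param seed Integer seed for the first cohort; cohort `i` uses
#'   `seed + i - 1`.
#' @param ... Further arguments passed to [simulate_cohort()].
#' @return A list of `fmt_cohort` objects (length `nsim`).
#' @export
simulate.fmt_engraftment <- function(object, nsim = 1, seed = 1, ...) {
  pi_hat <- object$summary$rates$mean / 100
  lapply(seq_len(nsim), function(i) {
    simulate_cohort(n_triads = nrow(object$triads),
                    engraft_prob = pi_hat, seed = seed + i - 1, ...)
  })
}
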