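# Result writers. Every table carries a '# ' comment header with the package
# version and a config fingerprint so outputs are traceable to the run that
# produced them; the JSON manifest records the full configuration.

#' Write all result tables of a fitted engraftment analysis
#'
#' Emits `engraftment_rates.tsv` (one row per triad),
#' `provenance_fractions.tsv` (two rows per triad: pre and post),
#' `engrafted_taxa.tsv` (when taxonomy was supplied), `cohort_summary.tsv`,
#' `correlations.tsv` and a `manifest.json` echoing the key statistics, the
#' package version and a configuration hash.
#'
#' @param fit An `fmt_engraftment` object.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(fit, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  cfg_hash <- .config_hash(fit$call)
  hdr <- sprintf("# fmtengraft %s | config %s", .pkg_version(), cfg_hash)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }

  paths <- c(rates = tsv(fit$rates, "engraftment_rates.tsv"),
             partitions = tsv(fit$partitions, "provenance_fractions.tsv"),
             summary = tsv(.summary_df(fit$summary), "cohort_summary.tsv"),
             correlations = tsv(.correlation_df(fit), "correlations.tsv"))
  if (!is.null(fit$taxa)) {
    paths <- c(paths, taxa = tsv(fit$taxa, "engrafted_taxa.tsv"))
  }

  manifest <- list(
    package = "fmtengraft",
    version = .pkg_version(),
    config_hash = cfg_hash,
    n_triads = nrow(fit$triads),
    n_asvs = fit$n_asvs,
    n_rare_asvs_removed = fit$filter_report$n_asvs_removed,
    rates = fit$summary$rates,
    mean_fractions = lapply(fit$summary$mean_fractions, as.list),
    overlap_correlation = fit$correlation,
    similarity_metric = fit$similarity_metric,
    tests = fit$summary$tests)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(c(paths, manifest = manifest_path))
}

#' Write the per-sample alpha diversity table
#'
#' @param alpha data.frame from [alpha_diversity()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alpha_diversity <- function(alpha, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fmtengraft ", .pkg_version(), " alpha diversity"), con)
  utils::write.table(alpha, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the preprocessing report
#'
#' Records the rare-ASV filter outcome and any samples excluded during
#' rarefaction in `preprocess_report.tsv` form.
#'
#' @param filter_report Report list from [remove_rare_asvs()].
#' @param excluded_samples Character vector of samples excluded by
#'   [rarefy()] (optional).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_preprocess_report <- function(filter_report, excluded_samples = character(),
                                    path) {
  df <- rbind(
    data.frame(item = "n_asvs_before",
               value = filter_report$n_asvs_before),
    data.frame(item = "n_asvs_removed",
               value = filter_report$n_asvs_removed),
    if (length(filter_report$removed_ids) > 0L)
      data.frame(item = "removed_asv",
                 value = filter_report$removed_ids),
    if (length(excluded_samples) > 0L)
      data.frame(item = "excluded_sample", value = excluded_samples))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fmtengraft ", .pkg_version(), " preprocess report"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.summary_df <- function(s) {
  data.frame(
    statistic = c("mean_rate_percent", "median_rate_percent",
                  "min_rate_percent", "max_rate_percent",
                  "n_defined", "n_undefined",
                  paste0("pre_", sub("fraction_", "",
                                     names(s$mean_fractions$preFMT))),
                  paste0("post_", sub("fraction_", "",
                                      names(s$mean_fractions$postFMT)))),
    value = c(s$rates$mean, s$rates$median, s$rates$min, s$rates$max,
              s$rates$n_defined, s$rates$n_undefined,
              unname(s$mean_fractions$preFMT),
              unname(s$mean_fractions$postFMT)),
    stringsAsFactors = FALSE)
}

.correlation_df <- function(fit) {
  data.frame(
    variable_x = paste0("donor_recipient_", fit$similarity_metric,
                        "_similarity"),
    variable_y = "post_donor_derived_fraction",
    rho = fit$correlation$rho,
    p_value = fit$correlation$p_value,
    n = fit$correlation$n,
    stringsAsFactors = FALSE)
}

# Tiny deterministic fingerprint of a configuration (call or list).
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = " ")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
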