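#' Read sample metadata
#'
#' Parses the per-sample metadata table describing each fecal sample: which
#' dog it came from, its role in the transplant design (`donor`, `preFMT` or
#' `postFMT`), the donor each recipient was assigned to, and optional host
#' covariates (clinical signs, raw food / kibble flags, prior antibiotic use,
#' body condition score).
#'
#' Role labels are normalised case-insensitively (`"Donor"`, `"PREfmt"`,
#' `"post_FMT"` all accepted). Recipient rows (roles `preFMT`/`postFMT`) must
#' carry a `donor_id`.
#'
#' @param path Tab-delimited file with a header row; required columns
#'   `sample_id`, `dog_id`, `role`; recognised optional columns `donor_id`,
#'   `donor_primary`, `clinical_signs`, `raw_food`, `kibble`,
#'   `prior_antibiotics`, `body_condition_score`.
#' @return A data.frame with one row per sample and normalised `role` values.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^# ", lines) & nzchar(lines)]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "dog_id", "role")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  key <- gsub("[^a-z]", "", tolower(df$role))
  role_map <- c(donor = "donor", prefmt = "preFMT", pre = "preFMT",
                postfmt = "postFMT", post = "postFMT")
  if (any(!key %in% names(role_map))) {
    stop("unrecognised role value(s): ",
         paste(unique(df$role[!key %in% names(role_map)]), collapse = ", "),
         call. = FALSE)
  }
  df$role <- unname(role_map[key])

  if (!"donor_id" %in% names(df)) df$donor_id <- NA_character_
  df$donor_id[!nzchar(trimws(ifelse(is.na(df$donor_id), "", df$donor_id)))] <-
    NA_character_
  recip <- df$role != "donor"
  if (any(recip & is.na(df$donor_id))) {
    stop("recipient row(s) missing donor_id: ",
         paste(df$sample_id[recip & is.na(df$donor_id)], collapse = ", "),
         call. = FALSE)
  }
  if ("donor_primary" %in% names(df)) {
    df$donor_primary <- tolower(trimws(df$donor_primary)) %in%
      c("true", "t", "yes", "y", "1")
  }
  if ("body_condition_score" %in% names(df)) {
    bcs <- suppressWarnings(as.numeric(df$body_condition_score))
    bad <- !is.na(bcs) & (bcs < 1 | bcs > 9 | bcs != round(bcs))
    if (any(bad)) {
      stop("body_condition_score outside 1-9 for sample(s): ",
           paste(df$sample_id[bad], collapse = ", "), call. = FALSE)
    }
    df$body_condition_score <- as.integer(bcs)
  }
  for (flag in c("raw_food", "kibble", "prior_antibiotics")) {
    if (flag %in% names(df)) {
      df[[flag]] <- tolower(trimws(df[[flag]])) %in%
        c("true", "t", "yes", "y", "1")
    }
  }
  df
}

#' Read an ASV taxonomy table
#'
#' Seven-rank taxonomy (domain through species) for each ASV. Missing or empty
#' ranks become `"unclassified"`. If `asv_ids` is supplied, ASVs absent from
#' the file get an all-`"unclassified"` placeholder row so that every ASV in a
#' count table has an entry.
#'
#' @param path Tab-delimited file; first column `asv_id`, then up to seven
#'   rank columns (`domain`, `phylum`, `class`, `order`, `family`, `genus`,
#'   `species`).
#' @param asv_ids Optional character vector of ASV ids that must be covered.
#' @return data.frame with columns `asv_id` plus the seven ranks.
#' @export
read_taxonomy <- function(path, asv_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^# ", lines) & nzchar(lines)]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  names(df)[1L] <- "asv_id"
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  names(df) <- c("asv_id", tolower(names(df)[-1L]))
  for (r in ranks) if (!r %in% names(df)) df[[r]] <- "unclassified"
  df <- df[, c("asv_id", ranks)]
  for (r in ranks) {
    v <- trimws(df[[r]])
    v[is.na(v) | !nzchar(v) | v %in% c("NA", "na")] <- "unclassified"
    df[[r]] <- v
  }
  if (anyDuplicated(df$asv_id)) {
    stop("duplicate asv_id in taxonomy: ",
         paste(unique(df$asv_id[duplicated(df$asv_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(asv_ids)) {
    absent <- setdiff(asv_ids, df$asv_id)
    if (length(absent) > 0L) {
      pad <- data.frame(asv_id = absent, stringsAsFactors = FALSE)
      for (r in ranks) pad[[r]] <- "unclassified"
      df <- rbind(df, pad)
    }
  }
  rownames(df) <- NULL
  df
}

#' Assemble donor / pre-FMT / post-FMT triads
#'
#' Pairs each recipient's pre-FMT and post-FMT samples with one donor sample,
#' the analysis unit for all engraftment computations. Each recipient dog must
#' have exactly one `preFMT` and one `postFMT` sample, both pointing at the
#' same known donor.
#'
#' Donors with several fecal samples are resolved by `donor_policy`:
#' \describe{
#'   \item{`"single"`}{use the metadata-flagged sample (`donor_primary` column);
#'     a donor with one sample needs no flag.}
#'   \item{`"pool"`}{sum that donor's samples element-wise into one
#'     pseudo-sample named `<donor_id>__pooled` (appended to the returned
#'     table).}
#'   \item{`"error"`}{abort if any donor has more than one sample.}
#' }
#'
#' @param counts Validated ASV count matrix (samples x ASVs).
#' @param metadata data.frame from [read_metadata()].
#' @param donor_policy `"single"`, `"pool"` or `"error"`.
#' @return A list with `triads` (data.frame: `recipient_id`, `donor_id`,
#'   `donor_sample`, `pre_sample`, `post_sample`) and `counts` (the input
#'   matrix, augmented with pooled donor pseudo-samples under
#'   `donor_policy = "pool"`).
#' @export
assemble_triads <- function(counts, metadata,
                            donor_policy = c("single", "pool", "error")) {
  donor_policy <- match.arg(donor_policy)
  counts <- validate_asv_table(counts)
  missing_samples <- setdiff(metadata$sample_id, rownames(counts))
  if (length(missing_samples) > 0L) {
    stop("metadata sample(s) absent from count table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }

  donors <- metadata[metadata$role == "donor", , drop = FALSE]
  donor_sample_for <- function(donor_id) {
    rows <- donors[donors$dog_id == donor_id, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("unknown donor_id '", donor_id, "': no donor sample in metadata",
           call. = FALSE)
    }
    if (nrow(rows) == 1L) return(rows$sample_id)
    switch(donor_policy,
      error = stop("donor '", donor_id, "' has ", nrow(rows),
                   " samples and donor_policy = 'error'", call. = FALSE),
      single = {
        if (!"donor_primary" %in% names(rows) || sum(rows$donor_primary) != 1L) {
          stop("donor '", donor_id, "' has ", nrow(rows), " samples; ",
               "donor_policy = 'single' requires exactly one donor_primary flag",
               call. = FALSE)
        }
        rows$sample_id[rows$donor_primary]
      },
      pool = paste0(donor_id, "__pooled"))
  }

  if (donor_policy == "pool") {
    for (d in unique(donors$dog_id)) {
      ids <- sort(donors$sample_id[donors$dog_id == d])
      if (length(ids) > 1L) {
        pooled <- colSums(counts[ids, , drop = FALSE])
        counts <- rbind(counts, matrix(pooled, nrow = 1,
                                       dimnames = list(paste0(d, "__pooled"),
                                                       colnames(counts))))
      } else {
        # single-sample donors keep their own sample
      }
    }
    donor_sample_for <- local({
      base <- donor_sample_for
      function(donor_id) {
        ids <- donors$sample_id[donors$dog_id == donor_id]
        if (length(ids) == 0L) base(donor_id)  # triggers unknown-donor error
        else if (length(ids) == 1L) ids
        else paste0(donor_id, "__pooled")
      }
    })
  }

  recip <- metadata[metadata$role != "donor", , drop = FALSE]
  dogs <- sort(unique(recip$dog_id))
  triads <- lapply(dogs, function(dog) {
    rows <- recip[recip$dog_id == dog, , drop = FALSE]
    pre <- rows$sample_id[rows$role == "preFMT"]
    post <- rows$sample_id[rows$role == "postFMT"]
    if (length(pre) != 1L || length(post) != 1L) {
      stop("recipient '", dog, "' must have exactly one preFMT and one ",
           "postFMT sample (found ", length(pre), " pre, ", length(post),
           " post)", call. = FALSE)
    }
    donor_id <- unique(rows$donor_id)
    if (length(donor_id) != 1L) {
      stop("recipient '", dog, "' has inconsistent donor_id values: ",
           paste(donor_id, collapse = ", "), call. = FALSE)
    }
    data.frame(recipient_id = dog, donor_id = donor_id,
               donor_sample = donor_sample_for(donor_id),
               pre_sample = pre, post_sample = post,
               stringsAsFactors = FALSE)
  })
  triads <- do.call(rbind, triads)
  rownames(triads) <- NULL
  list(triads = triads, counts = counts)
}
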