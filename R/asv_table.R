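#' Validate an ASV count table
#'
#' An ASV table is a plain numeric matrix of sequencing read counts with
#' samples as rows and amplicon sequence variants (ASVs) as columns. Row and
#' column names are the sample and ASV identifiers and are treated as opaque
#' strings. All entries must be non-negative integers.
#'
#' @param counts A matrix (or object coercible to one) of read counts,
#'   samples x ASVs, with complete, unique dimnames.
#' @return The validated count matrix (numeric, integral values), invisibly
#'   unchanged apart from coercion via [as.matrix()].
#' @export
validate_asv_table <- function(counts) {
  m <- as.matrix(counts)
  if (!is.numeric(m)) {
    stop("ASV table must be numeric; got mode '", mode(m), "'", call. = FALSE)
  }
  dn <- dimnames(m)
  if (is.null(dn) || is.null(dn[[1L]]) || is.null(dn[[2L]])) {
    stop("ASV table must carry sample ids (rownames) and ASV ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate ASV ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(m) | m < 0 | abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "ASV table contains %d invalid count(s); first offender: sample '%s', ASV '%s', value %s (counts must be non-negative integers)",
      nrow(bad), rownames(m)[i], colnames(m)[j], format(m[i, j])),
      call. = FALSE)
  }
  m
}

#' Read an ASV count table from a tab-delimited file
#'
#' Reads a samples x ASVs (or ASVs x samples) count matrix from TSV, including
#' the classic BIOM TSV export (leading `# Constructed from biom file` comment
#' and an `#OTU ID` header). Lines beginning with `"# "` are treated as
#' comments and skipped; a header starting with `#OTU` is kept.
#'
#' Orientation is normalised to samples x ASVs. With `orientation = "auto"`
#' and `sample_ids` supplied (e.g. from [read_metadata()]), the axis whose
#' labels intersect the known sample ids is taken as the sample axis; an
#' ambiguous or empty intersection is an error. Without `sample_ids`, rows are
#' assumed to be samples.
#'
#' @param path Path to a tab-delimited text file with one header row and the
#'   first column holding row identifiers.
#' @param orientation One of `"auto"`, `"samples_are_rows"`,
#'   `"samples_are_columns"`.
#' @param sample_ids Optional character vector of known sample ids used by
#'   orientation auto-detection.
#' @return A validated count matrix, samples x ASVs.
#' @seealso [write_asv_table()], [read_metadata()]
#' @export
read_asv_table <- function(path,
                           orientation = c("auto", "samples_are_rows",
                                           "samples_are_columns"),
                           sample_ids = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^# ", lines) & nzchar(lines)]
  if (length(lines) < 2L) stop("no tabular content in ", path, call. = FALSE)
  # BIOM-style header "#OTU ID<TAB>..." -- strip the leading '#'
  lines[1L] <- sub("^#", "", lines[1L])
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids

  flip <- switch(orientation,
    samples_are_rows = FALSE,
    samples_are_columns = TRUE,
    auto = {
      if (is.null(sample_ids)) {
        FALSE
      } else {
        in_rows <- length(intersect(rownames(m), sample_ids))
        in_cols <- length(intersect(colnames(m), sample_ids))
        if (in_rows == in_cols) {
          stop("cannot auto-detect orientation: sample ids match ",
               in_rows, " row label(s) and ", in_cols, " column label(s)",
               call. = FALSE)
        }
        in_cols > in_rows
      }
    })
  if (flip) m <- t(m)
  validate_asv_table(m)
}

#' Write an ASV count table to TSV
#'
#' Emits a tab-delimited samples x ASVs matrix with a `# ` comment header
#' recording the package version, so that [read_asv_table()] round-trips the
#' counts exactly.
#'
#' @param counts Validated ASV count matrix (samples x ASVs).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(counts, path) {
  counts <- validate_asv_table(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fmtengraft ", .pkg_version(), " ASV count table"), con)
  writeLines(paste(c("sample_id", colnames(counts)), collapse = "\t"), con)
  body <- apply(counts, 1L, function(r) paste(format(r, scientific = FALSE,
                                                     trim = TRUE),
                                              collapse = "\t"))
  writeLines(paste(rownames(counts), body, sep = "\t"), con)
  invisible(path)
}

.pkg_version <- function() {
  as.character(utils::packageVersion("fmtengraft"))
}
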