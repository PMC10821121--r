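# Synthetic FMT cohort generator. Emulates the structure of an oral-capsule
# FMT study in dogs: a handful of donors each serving several recipients,
# long-tailed (log-normal) community profiles, tunable donor-recipient taxon
# overlap, per-ASV engraftment with a known probability, persistence of the
# recipient's own taxa, environmental influx, and multinomial read sampling
# at realistic 16S depths. Ground-truth source labels are recorded for every
# post-FMT taxon so that the whole pipeline can be validated against truth.

#' Simulate a log-normal community profile
#'
#' Relative abundances proportional to `exp(N(0, sigma^2))` i.i.d. draws,
#' normalised to sum to 1 — the standard long-tailed rank-abundance model for
#' gut communities. `sigma = 0` degenerates to a uniform profile.
#'
#' @param richness Number of taxa (>= 1).
#' @param sigma Log-scale standard deviation (default 1.5).
#' @return Numeric vector of relative abundances summing to 1.
#' @export
simulate_community <- function(richness, sigma = 1.5) {
  if (richness < 1) stop("richness must be >= 1", call. = FALSE)
  a <- exp(stats::rnorm(richness, 0, sigma))
  a / sum(a)
}

#' Simulate a random rooted bifurcating phylogeny over ASVs
#'
#' Random bifurcating topology with independent Exponential(1) branch
#' lengths, suitable as a stand-in ASV tree for UniFrac. Uses the current RNG
#' stream; wrap in a seed for reproducibility.
#'
#' @param asv_ids Character vector of leaf labels (>= 2).
#' @return An [ape::phylo] tree with `length(asv_ids) - 1` internal nodes.
#' @export
simulate_tree <- function(asv_ids) {
  n <- length(asv_ids)
  if (n < 2L) stop("need at least 2 ASV ids to build a tree", call. = FALSE)
  ape::rtree(n, rooted = TRUE, tip.label = asv_ids, br = stats::rexp)
}

#' Simulate one donor / pre-FMT / post-FMT triad
#'
#' The pre-FMT community shares a fraction `overlap` of its taxa with the
#' donor; the post-FMT community keeps each pre-FMT taxon with probability
#' `persist_prob`, engrafts each eligible donor taxon (donor-only)
#' independently with probability `engraft_prob` at `engraft_strength` times
#' its donor relative abundance, adds `n_env` novel low-abundance
#' environmental taxa, renormalises, and draws reads. The true source class
#' of every post-FMT taxon is returned.
#'
#' @param donor Named numeric vector of donor relative abundances (names are
#'   ASV ids).
#' @param pool Character vector of ASV ids the recipient and environment can
#'   draw novel taxa from (taxa in `donor` are excluded where appropriate).
#' @param recipient_richness Integer range (length-2) or scalar richness of
#'   the pre-FMT community.
#' @param overlap Fraction of pre-FMT taxa drawn from the donor's taxa.
#' @param engraft_prob Per-ASV engraftment probability for eligible donor
#'   taxa.
#' @param persist_prob Probability each pre-FMT taxon persists post-FMT.
#' @param n_env Number of novel environmental taxa added post-FMT.
#' @param env_abundance Mean relative abundance (pre-normalisation) of each
#'   environmental taxon.
#' @param engraft_strength Relative-abundance multiplier applied to the donor
#'   abundance of newly engrafted taxa.
#' @param lognormal_sigma Log-normal sigma of the pre-FMT profile.
#' @param depth Read depth: a scalar, or a length-2 range sampled uniformly
#'   per sample.
#' @param multinomial If `TRUE` (default) draw multinomial counts, so
#'   low-abundance taxa can drop out as in real sequencing; if `FALSE`,
#'   produce deterministic counts that preserve presence exactly (every taxon
#'   with positive true abundance gets >= 1 read).
#' @return List: `donor_counts`, `pre_counts`, `post_counts` (named integer
#'   vectors) and `truth` (list: `classes` — named vector over true post-FMT
#'   taxa with values `always_shared`/`donor_derived`/`recipient_derived`/
#'   `environmental` — plus `eligible_set`, `engrafted_set`, `engraft_prob`).
#' @export
simulate_triad <- function(donor, pool,
                           recipient_richness = c(40, 180),
                           overlap = 0.6,
                           engraft_prob = 0.18,
                           persist_prob = 0.9,
                           n_env = 20,
                           env_abundance = 0.006,
                           engraft_strength = 0.5,
                           lognormal_sigma = 1.5,
                           depth = c(26000, 60000),
                           multinomial = TRUE) {
  donor_taxa <- names(donor)
  r_rich <- .draw_in_range(recipient_richness)
  n_shared <- min(round(overlap * r_rich), length(donor_taxa))
  shared <- sample(donor_taxa, n_shared)
  novel_pool <- setdiff(pool, donor_taxa)
  own <- sample(novel_pool, r_rich - n_shared)
  pre_taxa <- c(shared, own)
  pre <- stats::setNames(simulate_community(r_rich, lognormal_sigma), pre_taxa)

  # post-FMT assembly: persistence, engraftment, environmental influx
  persisted <- pre[stats::runif(length(pre)) < persist_prob]
  eligible <- setdiff(donor_taxa, pre_taxa)
  engrafted <- eligible[stats::runif(length(eligible)) < engraft_prob]
  engrafted_abund <- stats::setNames(
    donor[engrafted] * engraft_strength, engrafted)
  env_pool <- setdiff(novel_pool, pre_taxa)
  env_taxa <- sample(env_pool, min(n_env, length(env_pool)))
  env_abund <- stats::setNames(
    env_abundance * exp(stats::rnorm(length(env_taxa), 0, 0.5)), env_taxa)

  post <- c(persisted, engrafted_abund, env_abund)
  post <- post / sum(post)

  classes <- c(
    stats::setNames(ifelse(names(persisted) %in% donor_taxa,
                           "always_shared", "recipient_derived"),
                    names(persisted)),
    stats::setNames(rep("donor_derived", length(engrafted)), engrafted),
    stats::setNames(rep("environmental", length(env_taxa)), env_taxa))

  list(
    donor_counts = .draw_counts(donor, .draw_in_range(depth), multinomial),
    pre_counts = .draw_counts(pre, .draw_in_range(depth), multinomial),
    post_counts = .draw_counts(post, .draw_in_range(depth), multinomial),
    truth = list(classes = classes,
                 eligible_set = eligible,
                 engrafted_set = engrafted,
                 engraft_prob = engraft_prob))
}

#' Simulate a full synthetic FMT cohort with ground truth
#'
#' Generates a donor pool, recipient triads assigned round-robin to donors, a
#' random ASV phylogeny, synthetic taxonomy drawn from a dog-gut genus
#' vocabulary, and per-triad ground-truth provenance labels. Defaults mirror
#' a 54-recipient, 7-donor oral-capsule FMT study design: donor richness
#' 33-170 ASVs, sequencing depth 26000-60000 reads, ~60% donor-recipient
#' taxon overlap and an 18% per-ASV engraftment probability.
#'
#' @inheritParams simulate_triad
#' @param n_triads Number of recipients.
#' @param n_donors Number of distinct donors (recipients assigned
#'   round-robin).
#' @param donor_richness Integer range of donor community richness.
#' @param n_pool Size of the global ASV pool communities draw from.
#' @param seed Integer seed; all randomness flows from it and the caller RNG
#'   is untouched.
#' @return Object of class `fmt_cohort`: list with `counts` (samples x ASVs
#'   matrix covering all observed taxa), `metadata`, `taxonomy`, `tree`
#'   ([ape::phylo] over the observed taxa), `truth` (per-recipient list as in
#'   [simulate_triad()]), and `params`.
#' @export
simulate_cohort <- function(n_triads = 54,
                            n_donors = 7,
                            donor_richness = c(33, 170),
                            recipient_richness = c(40, 180),
                            overlap = 0.6,
                            engraft_prob = 0.18,
                            persist_prob = 0.9,
                            n_env = 20,
                            env_abundance = 0.006,
                            engraft_strength = 0.5,
                            lognormal_sigma = 1.5,
                            depth = c(26000, 60000),
                            n_pool = 1000,
                            multinomial = TRUE,
                            seed = 1) {
  stopifnot(n_triads >= 1, n_donors >= 1,
            overlap >= 0, overlap <= 1,
            engraft_prob >= 0, engraft_prob <= 1,
            persist_prob >= 0, persist_prob <= 1,
            all(depth > 0))
  params <- list(n_triads = n_triads, n_donors = n_donors,
                 donor_richness = donor_richness,
                 recipient_richness = recipient_richness, overlap = overlap,
                 engraft_prob = engraft_prob, persist_prob = persist_prob,
                 n_env = n_env, env_abundance = env_abundance,
                 engraft_strength = engraft_strength,
                 lognormal_sigma = lognormal_sigma, depth = depth,
                 n_pool = n_pool, multinomial = multinomial, seed = seed)

  with_seed(seed, {
    pool <- sprintf("ASV%04d", seq_len(n_pool))
    taxonomy <- .simulate_taxonomy(pool)

    donors <- lapply(seq_len(n_donors), function(d) {
      rich <- .draw_in_range(donor_richness)
      taxa <- sample(pool, rich)
      stats::setNames(simulate_community(rich, lognormal_sigma), taxa)
    })
    donor_ids <- sprintf("donor%d", seq_len(n_donors))
    donor_samples <- sprintf("donor%d_s1", seq_len(n_donors))
    donor_counts <- lapply(donors, .draw_counts,
                           depth = NULL, multinomial = multinomial,
                           depth_range = depth)

    assignment <- rep_len(seq_len(n_donors), n_triads)
    recipients <- sprintf("dog%02d", seq_len(n_triads))

    rows <- list()
    truth <- list()
    for (i in seq_len(n_triads)) {
      d <- assignment[i]
      tri <- simulate_triad(
        donors[[d]], pool,
        recipient_richness = recipient_richness, overlap = overlap,
        engraft_prob = engraft_prob, persist_prob = persist_prob,
        n_env = n_env, env_abundance = env_abundance,
        engraft_strength = engraft_strength,
        lognormal_sigma = lognormal_sigma, depth = depth,
        multinomial = multinomial)
      rows[[paste0(recipients[i], "_pre")]] <- tri$pre_counts
      rows[[paste0(recipients[i], "_post")]] <- tri$post_counts
      truth[[recipients[i]]] <- tri$truth
    }
    for (d in seq_len(n_donors)) {
      rows[[donor_samples[d]]] <- donor_counts[[d]]
    }

    counts <- matrix(0L, nrow = length(rows), ncol = n_pool,
                     dimnames = list(names(rows), pool))
    for (s in names(rows)) {
      counts[s, names(rows[[s]])] <- rows[[s]]
    }
    observed <- colSums(counts) > 0
    counts <- counts[, observed, drop = FALSE]
    taxonomy <- taxonomy[taxonomy$asv_id %in% colnames(counts), , drop = FALSE]
    rownames(taxonomy) <- NULL

    metadata <- rbind(
      data.frame(sample_id = donor_samples, dog_id = donor_ids,
                 role = "donor", donor_id = NA_character_,
                 stringsAsFactors = FALSE),
      data.frame(sample_id = c(rbind(paste0(recipients, "_pre"),
                                     paste0(recipients, "_post"))),
                 dog_id = rep(recipients, each = 2L),
                 role = rep(c("preFMT", "postFMT"), times = n_triads),
                 donor_id = rep(donor_ids[assignment], each = 2L),
                 stringsAsFactors = FALSE))
    rownames(metadata) <- NULL

    tree <- simulate_tree(colnames(counts))

    structure(list(counts = counts, metadata = metadata,
                   taxonomy = taxonomy, tree = tree, truth = truth,
                   params = params),
              class = "fmt_cohort")
  })
}

#' @export
print.fmt_cohort <- function(x, ...) {
  cat("Synthetic FMT cohort:", length(x$truth), "triads,",
      sum(x$metadata$role == "donor"), "donor samples,",
      ncol(x$counts), "observed ASVs\n")
  cat("  engraftment probability:", x$params$engraft_prob,
      "| overlap:", x$params$overlap,
      "| seed:", x$params$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk` and
#' `truth.json` into `out_dir`, directly consumable by [read_asv_table()],
#' [read_taxonomy()], [read_metadata()] and [read_newick()].
#'
#' @param cohort An `fmt_cohort` object from [simulate_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             taxonomy = file.path(out_dir, "taxonomy.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             truth = file.path(out_dir, "truth.json"))
  write_asv_table(cohort$counts, paths[["counts"]])
  .write_tsv(cohort$taxonomy, paths[["taxonomy"]])
  .write_tsv(cohort$metadata, paths[["metadata"]])
  write_newick(cohort$tree, paths[["tree"]])
  truth <- list(seed = cohort$params$seed, params = cohort$params,
                triads = cohort$truth)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(paths)
}

# -- internals ---------------------------------------------------------------

.draw_in_range <- function(x) {
  if (length(x) == 1L) return(x)
  sample(seq.int(x[1L], x[2L]), 1L)
}

.draw_counts <- function(prob, depth, multinomial, depth_range = NULL) {
  if (is.null(depth)) depth <- .draw_in_range(depth_range)
  p <- prob / sum(prob)
  if (multinomial) {
    counts <- stats::rmultinom(1L, depth, p)[, 1L]
  } else {
    counts <- pmax(1L, round(p * depth))
  }
  stats::setNames(as.integer(counts), names(prob))
}

# Dog-gut family/genus vocabulary with consistent upper lineages; genus
# "unclassified" rows exercise the lowest-classified-rank labelling.
.dog_gut_taxa <- function() {
  lineages <- list(
    c("Firmicutes", "Clostridia", "Lachnospirales", "Lachnospiraceae"),
    c("Firmicutes", "Clostridia", "Oscillospirales", "Ruminococcaceae"),
    c("Bacteroidota", "Bacteroidia", "Bacteroidales", "Bacteroidaceae"),
    c("Bacteroidota", "Bacteroidia", "Bacteroidales", "Prevotellaceae"),
    c("Fusobacteriota", "Fusobacteriia", "Fusobacteriales",
      "Fusobacteriaceae"),
    c("Firmicutes", "Negativicutes", "Selenomonadales", "Selenomonadaceae"),
    c("Proteobacteria", "Gammaproteobacteria", "Burkholderiales",
      "Sutterellaceae"),
    c("Firmicutes", "Clostridia", "Peptostreptococcales",
      "Peptostreptococcaceae"),
    c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae"),
    c("Proteobacteria", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae"),
    c("Firmicutes", "Clostridia", "Oscillospirales", "Butyricicoccaceae"),
    c("Actinobacteriota", "Coriobacteriia", "Coriobacteriales",
      "Coriobacteriaceae"),
    c("Firmicutes", "Bacilli", "Erysipelotrichales", "Erysipelotrichaceae"))
  genera <- list(
    c("Blautia", "Lachnoclostridium", "uncultured Lachnospiraceae",
      "Roseburia", "Dorea"),
    c("Faecalibacterium", "Ruminococcus torques group", "unclassified"),
    c("Bacteroides"),
    c("Prevotella 9", "Alloprevotella"),
    c("Fusobacterium"),
    c("Megamonas"),
    c("Sutterella"),
    c("Peptoclostridium", "Romboutsia"),
    c("Streptococcus"),
    c("Escherichia-Shigella"),
    c("Butyricicoccus"),
    c("Collinsella"),
    c("Allobaculum", "Turicibacter"))
  do.call(rbind, lapply(seq_along(lineages), function(i) {
    data.frame(phylum = lineages[[i]][1L], class = lineages[[i]][2L],
               order = lineages[[i]][3L], family = lineages[[i]][4L],
               genus = genera[[i]], stringsAsFactors = FALSE)
  }))
}

.simulate_taxonomy <- function(asv_ids) {
  vocab <- .dog_gut_taxa()
  pick <- sample(nrow(vocab), length(asv_ids), replace = TRUE)
  data.frame(asv_id = asv_ids,
             domain = "Bacteria",
             phylum = vocab$phylum[pick],
             class = vocab$class[pick],
             order = vocab$order[pick],
             family = vocab$family[pick],
             genus = vocab$genus[pick],
             species = "unclassified",
             stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# fmtengraft ", .pkg_version()), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
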