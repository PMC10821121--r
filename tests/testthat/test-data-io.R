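test_that("ASV table validation catches bad counts and duplicate ids", {
  m <- tiny_triad_counts()
  expect_identical(validate_asv_table(m), m)

  bad <- m
  bad["pre1", "a"] <- -1
  expect_error(validate_asv_table(bad), "pre1.*'a'|'a'.*pre1")

  frac <- m
  frac["D1", "b"] <- 2.5
  expect_error(validate_asv_table(frac), "non-negative integers")

  dup <- m
  rownames(dup)[2] <- "D1"
  expect_error(validate_asv_table(dup), "duplicate sample ids")
  dup2 <- m
  colnames(dup2)[2] <- "a"
  expect_error(validate_asv_table(dup2), "duplicate ASV ids")
})

test_that("ASV table TSV round-trip preserves counts bit-exactly", {
  m <- random_counts(3, 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(m, path)
  back <- read_asv_table(path)
  expect_identical(dim(back), dim(m))
  expect_identical(dimnames(back), dimnames(m))
  expect_true(all(back == m))
})

test_that("BIOM-style TSV exports are read, comments skipped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# Constructed from biom file",
               "#OTU ID\ts1\ts2",
               "asvA\t3\t0",
               "asvB\t1\t7"), path)
  m <- read_asv_table(path, sample_ids = c("s1", "s2"))
  expect_identical(sort(rownames(m)), c("s1", "s2"))
  expect_equal(m["s2", "asvB"], 7)
})

test_that("orientation auto-detection uses metadata sample ids and flags ambiguity", {
  m <- random_counts(3, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(t(m), path)  # ASVs as rows on disk
  back <- read_asv_table(path, sample_ids = rownames(m))
  expect_identical(rownames(back), rownames(m))
  expect_true(all(back == m))
  expect_error(read_asv_table(path, sample_ids = c("nope1", "nope2")),
               "auto-detect")
})

test_that("metadata roles are normalised and recipient donor links enforced", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tdog_id\trole\tdonor_id",
               "D1\tdonorA\tDonor\t",
               "pre1\tdog1\tPreFMT\tdonorA",
               "post1\tdog1\tpost_FMT\tdonorA"), path)
  md <- read_metadata(path)
  expect_identical(md$role, c("donor", "preFMT", "postFMT"))

  writeLines(c("sample_id\tdog_id\trole\tdonor_id",
               "pre1\tdog1\tpreFMT\t"), path)
  expect_error(read_metadata(path), "missing donor_id.*pre1")
})

test_that("triad assembly builds one triad per recipient and pools donors additively", {
  m <- tiny_triad_counts()
  asm <- assemble_triads(m, tiny_metadata())
  expect_identical(nrow(asm$triads), 1L)
  expect_identical(asm$triads$donor_sample, "D1")
  expect_identical(asm$triads$pre_sample, "pre1")

  # donor with two samples: pooling sums counts elementwise and the result
  # is invariant to sample order in the metadata/table
  m2 <- rbind(m, D2 = c(1L, 2L, 3L, 4L, 5L, 6L))
  md2 <- rbind(tiny_metadata(),
               data.frame(sample_id = "D2", dog_id = "donorA", role = "donor",
                          donor_id = NA, stringsAsFactors = FALSE))
  pooled <- assemble_triads(m2, md2, donor_policy = "pool")
  expect_identical(pooled$triads$donor_sample, "donorA__pooled")
  expect_equal(unname(pooled$counts["donorA__pooled", ]),
               unname(m2["D1", ] + m2["D2", ]))
  shuffled <- assemble_triads(m2[c(4, 2, 1, 3), ], md2[c(4, 1, 2, 3), ],
                              donor_policy = "pool")
  expect_equal(pooled$counts["donorA__pooled", ],
               shuffled$counts["donorA__pooled", ])

  expect_error(assemble_triads(m2, md2, donor_policy = "error"),
               "donor_policy = 'error'")
  expect_error(assemble_triads(m2, md2, donor_policy = "single"),
               "donor_primary")

  # missing post sample
  md3 <- tiny_metadata()[1:2, ]
  expect_error(assemble_triads(m, md3), "exactly one preFMT and one postFMT")

  # unknown donor
  md4 <- tiny_metadata()
  md4$donor_id[2:3] <- "ghost"
  expect_error(assemble_triads(m, md4), "unknown donor_id 'ghost'")
})

test_that("Newick reading enforces lengths and round-trips simulated trees", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:2);", path)
  tr <- read_newick(path)
  expect_identical(sort(tr$tip.label), c("a", "b", "c"))
  expect_equal(sum(tr$edge.length), 5)

  writeLines("((a,b),c);", path)
  expect_warning(tr2 <- read_newick(path), "defaulting all lengths to 1")
  expect_true(all(tr2$edge.length == 1))

  warns <- capture_warnings(read_newick(path, asv_ids = c("a", "b")))
  expect_match(warns, "match no known ASV id", all = FALSE)

  # write/read round-trip of a simulated 200-leaf tree is exact at the
  # Newick string level
  ids <- sprintf("ASV%03d", 1:200)
  tr3 <- fmtengraft:::with_seed(7, simulate_tree(ids))
  write_newick(tr3, path)
  first <- readLines(path)
  tr4 <- read_newick(path)
  write_newick(tr4, path)
  expect_identical(readLines(path), first)
})
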