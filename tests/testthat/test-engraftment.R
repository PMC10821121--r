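test_that("presence sets respect the threshold and reject unknown samples", {
  m <- matrix(c(0L, 3L, 1L), 1, dimnames = list("s1", c("a", "b", "c")))
  expect_identical(presence_set(m, "s1"), c("b", "c"))
  expect_identical(presence_set(m, "s1", min_presence = 2), "b")
  expect_error(presence_set(m, "nope"), "unknown sample")
  z <- matrix(0L, 1, 2, dimnames = list("s1", c("a", "b")))
  expect_warning(out <- presence_set(z, "s1"), "empty presence set")
  expect_length(out, 0)
})

test_that("engraftment rate matches manual set enumeration", {
  m <- tiny_triad_counts()  # D={a,b,c,d}, P={a,e}, Q={a,b,f}
  res <- engraftment_rate(tiny_triad(), m)
  expect_identical(sort(res$eligible_set), c("b", "c", "d"))
  expect_identical(res$engrafted_set, "b")
  expect_equal(res$rate_percent, 100 / 3, tolerance = 1e-9)
  expect_true(res$defined)
  expect_identical(res$donor_set_size, 4L)

  # Q superset of D with P disjoint from D -> 100%
  m2 <- m
  m2["post1", c("a", "b", "c", "d")] <- 1L
  m2["pre1", ] <- 0L
  m2["pre1", "e"] <- 3L
  res2 <- engraftment_rate(tiny_triad(), m2)
  expect_equal(res2$rate_percent, 100)

  # donor fully contained in pre -> undefined, flagged
  m3 <- m
  m3["pre1", c("a", "b", "c", "d")] <- 1L
  res3 <- engraftment_rate(tiny_triad(), m3)
  expect_false(res3$defined)
  expect_true(is.na(res3$rate_percent))
})

test_that("provenance classes and fractions follow the four-way definition", {
  # Q={a,b,e,f}, D={a,b,c}, P={a,e}
  m <- matrix(0L, 3, 6,
              dimnames = list(c("D1", "pre1", "post1"),
                              c("a", "b", "c", "e", "f", "g")))
  m["D1", c("a", "b", "c")] <- 10L
  m["pre1", c("a", "e")] <- 10L
  m["post1", c("a", "b", "e", "f")] <- c(4L, 3L, 2L, 1L)
  tri <- tiny_triad()
  cls <- classify_provenance(tri, m, "postFMT")
  expect_identical(cls[["a"]], "always_shared")
  expect_identical(cls[["b"]], "donor_derived")
  expect_identical(cls[["e"]], "recipient_derived")
  expect_identical(cls[["f"]], "environmental")

  pre_cls <- classify_provenance(tri, m, "preFMT")
  expect_setequal(names(pre_cls), c("a", "e"))
  expect_identical(unname(pre_cls[c("a", "e")]),
                   c("always_shared", "recipient_derived"))

  fr <- provenance_fractions(tri, m, "postFMT")
  expect_equal(fr$fraction_always_shared, 0.4)
  expect_equal(fr$fraction_donor_derived, 0.3)
  expect_equal(fr$fraction_recipient_derived, 0.2)
  expect_equal(fr$fraction_environmental, 0.1)

  # pre-FMT community contained in donor -> everything always-shared
  m2 <- m
  m2["pre1", ] <- 0L
  m2["pre1", c("a", "b")] <- 5L
  fr2 <- provenance_fractions(tri, m2, "preFMT")
  expect_equal(fr2$fraction_always_shared, 1)

  # D = P -> nothing can be donor-derived at any stage
  m3 <- m
  m3["pre1", ] <- m3["D1", ]
  expect_false("donor_derived" %in% classify_provenance(tri, m3, "postFMT"))
})

test_that("partition property holds on random tables", {
  set.seed(31)
  tri <- tiny_triad()
  for (i in 1:20) {
    m <- random_counts(3, 15, lambda = 1.5)
    dimnames(m) <- list(c("D1", "pre1", "post1"), paste0("asv", 1:15))
    if (any(rowSums(m) == 0)) next
    for (stage in c("preFMT", "postFMT")) {
      cls <- suppressWarnings(classify_provenance(tri, m, stage))
      s_id <- if (stage == "preFMT") "pre1" else "post1"
      expect_setequal(names(cls), colnames(m)[m[s_id, ] > 0])
      fr <- suppressWarnings(provenance_fractions(tri, m, stage))
      tot <- fr$fraction_always_shared + fr$fraction_donor_derived +
        fr$fraction_recipient_derived + fr$fraction_environmental
      expect_equal(tot, 1, tolerance = 1e-9)
      if (stage == "preFMT") {
        expect_equal(fr$fraction_donor_derived, 0)
        expect_equal(fr$fraction_environmental, 0)
      }
    }
  }
})

test_that("results are local and monotone in the post-FMT sample", {
  m <- tiny_triad_counts()
  tri <- tiny_triad()
  base <- engraftment_rate(tri, m)

  # adding unrelated samples and ASVs never changes the triad's result
  ext <- cbind(m, zz = c(0L, 0L, 0L))
  ext <- rbind(ext, other = c(9L, 9L, 9L, 9L, 9L, 9L, 9L))
  ext_res <- suppressWarnings(engraftment_rate(tri, ext))
  expect_identical(ext_res$eligible_set, base$eligible_set)
  expect_identical(ext_res$engrafted_set, base$engrafted_set)
  expect_equal(ext_res$rate_percent, base$rate_percent)

  # adding post-FMT ASVs can only keep or raise the rate
  set.seed(32)
  for (i in 1:10) {
    m2 <- m
    add <- sample(colnames(m), 2)
    m2["post1", add] <- m2["post1", add] + 5L
    expect_gte(engraftment_rate(tri, m2)$rate_percent, base$rate_percent)
  }
})

test_that("engraftment agrees with exhaustive enumeration on small random tables", {
  set.seed(33)
  tri <- tiny_triad()
  for (i in 1:30) {
    n <- sample(5:20, 1)
    m <- matrix(rbinom(3 * n, 3, 0.4), nrow = 3,
                dimnames = list(c("D1", "pre1", "post1"), paste0("a", 1:n)))
    if (any(rowSums(m) == 0)) next
    res <- suppressWarnings(engraftment_rate(tri, m))
    oracle <- bf_engraftment(m, "D1", "pre1", "post1")
    expect_setequal(res$eligible_set, oracle$eligible)
    expect_setequal(res$engrafted_set, oracle$engrafted)
    expect_equal(res$rate_percent, oracle$rate)
  }
})

test_that("taxon engraftment frequencies group by lowest classified rank", {
  taxonomy <- data.frame(
    asv_id = c("a1", "a2", "a3"),
    domain = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = c("Lachnospirales", "Lachnospirales", "Oscillospirales"),
    family = c("Lachnospiraceae", "Lachnospiraceae", "Ruminococcaceae"),
    genus = c("Blautia", "Blautia", "unclassified"),
    species = "unclassified", stringsAsFactors = FALSE)

  mk <- function(engrafted) {
    structure(list(recipient_id = "x", donor_set_size = 3L,
                   eligible_set = engrafted, engrafted_set = engrafted,
                   n_eligible = length(engrafted),
                   n_engrafted = length(engrafted),
                   rate_percent = 100, defined = TRUE),
              class = "engraftment_result")
  }
  out <- taxon_engraftment_frequency(list(mk("a1"), mk(c("a2", "a3"))),
                                     taxonomy)
  expect_identical(out$taxon[1], "Blautia")
  expect_identical(out$n_engraftment_events[1], 2L)
  expect_true("unclassified Ruminococcaceae" %in% out$taxon)
  expect_equal(sum(out$percent_of_all_events), 100, tolerance = 1e-6)
  expect_true(all(diff(out$n_engraftment_events) <= 0))

  empty <- taxon_engraftment_frequency(list(), taxonomy)
  expect_identical(nrow(empty), 0L)

  # uncultured genus labels are kept verbatim
  taxonomy$genus[1:2] <- "uncultured Lachnospiraceae"
  lbl <- taxon_label("a1", taxonomy)
  expect_identical(lbl, "uncultured Lachnospiraceae")
})
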