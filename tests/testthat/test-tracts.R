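lad5 <- polymorphism_ladder(c(12, 112, 209, 348, 460))

test_that("minimum tract length is the proximal-to-distal converted distance", {
  # conversion only at the 12 bp site: 1 bp minimum tract
  one <- tract_lengths(c("converted", rep("unconverted", 4)), lad5)
  expect_equal(one$min_bp, 1L)
  # conversions at 12 and 209: 198 bp
  two <- tract_lengths(c("converted", "unconverted", "converted",
                         "unconverted", "unconverted"), lad5)
  expect_equal(two$min_bp, 198L)
  # heteroduplex counts toward extent
  het <- tract_lengths(c("heteroduplex", "unconverted", "converted",
                         "unconverted", "unconverted"), lad5)
  expect_equal(het$min_bp, 198L)
  expect_error(tract_lengths(rep("unconverted", 5), lad5), "no converted")
  expect_error(tract_lengths(c("bogus", rep("unconverted", 4)), lad5),
               "unknown call")
})

test_that("minimum tract equals the scan-all-pairs oracle on random call vectors", {
  set.seed(21)
  lvls <- c("converted", "unconverted", "heteroduplex", "unreadable")
  for (i in 1:200) {
    calls <- sample(lvls, 5, replace = TRUE)
    expected <- oracle_min_tract(calls, lad5)
    if (is.na(expected)) {
      expect_error(tract_lengths(calls, lad5), "no converted")
    } else {
      expect_equal(tract_lengths(calls, lad5)$min_bp, expected)
    }
  }
})

test_that("maximum tract extends to flanking unconverted context and bounds the minimum", {
  # single conversion at 12, unconverted at 112: max spans (0, 112) = 111
  tl <- tract_lengths(c("converted", rep("unconverted", 4)), lad5)
  expect_equal(tl$max_bp, 111L)
  # no distal unconverted marker: bounded by ladder end + 1
  tl2 <- tract_lengths(rep("converted", 5), lad5)
  expect_equal(tl2$max_bp, 460L)
  expect_equal(tl2$min_bp, 449L)
  # unreadable positions are non-informative for both bounds
  tl3 <- tract_lengths(c("converted", "unreadable", "unconverted",
                         "unreadable", "unreadable"), lad5)
  expect_equal(tl3$max_bp, 208L)
  # min <= max over random vectors; adding a conversion never shrinks the span
  set.seed(31)
  for (i in 1:100) {
    calls <- sample(c("converted", "unconverted", "unreadable"), 5,
                    replace = TRUE, prob = c(0.5, 0.3, 0.2))
    if (!any(calls == "converted")) calls[1] <- "converted"
    tl <- tract_lengths(calls, lad5)
    expect_lte(tl$min_bp, tl$max_bp)
    grow_at <- which(calls != "converted")
    if (length(grow_at) > 0) {
      calls2 <- calls
      calls2[sample(grow_at, 1)] <- "converted"
      expect_gte(tract_lengths(calls2, lad5)$min_bp, tl$min_bp)
    }
  }
})

test_that("NCO/CO short-long classification matches definitions exhaustively", {
  lvls <- c("converted", "unconverted", "heteroduplex", "unreadable")
  grid <- expand.grid(rep(list(lvls), 5), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    calls <- unlist(grid[r, ], use.names = FALSE)
    conv <- lad5[calls %in% c("converted", "heteroduplex")]
    if (length(conv) == 0) {
      expect_error(classify_nco(calls, lad5))
      expect_error(classify_co(calls, lad5, recombinant_class = "CO"))
      next
    }
    # oracle: short NCO iff the only converted site is the 12 bp site
    expect_equal(classify_nco(calls, lad5),
                 if (identical(conv, lad5[1])) "short" else "long")
    # oracle: short CO iff scan-all-pairs minimum tract <= 198
    expect_equal(classify_co(calls, lad5, recombinant_class = "CO"),
                 if (oracle_min_tract(calls, lad5) <= 198) "short" else "long")
    # short NCO implies minimum tract of exactly 1 bp
    if (classify_nco(calls, lad5) == "short") {
      expect_equal(tract_lengths(calls, lad5)$min_bp, 1L)
    }
  }
})

test_that("CO threshold is inclusive at 198 bp", {
  lad <- polymorphism_ladder(c(12, 209, 210))
  expect_equal(classify_co(c("converted", "converted", "unconverted"),
                           lad, recombinant_class = "CO"), "short")  # 198
  expect_equal(classify_co(c("converted", "unconverted", "converted"),
                           lad, recombinant_class = "CO"), "long")   # 199
  expect_equal(classify_co(c("converted", "unconverted", "unconverted"),
                           lad, recombinant_class = "CO"), "short")  # 1
  # class guards
  expect_error(classify_nco(c("converted", "unconverted", "unconverted"),
                            lad, recombinant_class = "CO"), "NCO")
  expect_error(classify_co(c("converted", "unconverted", "unconverted"),
                           lad, recombinant_class = "NCO"), "CO")
})

test_that("heteroduplex detection is positional and warns on all-unreadable", {
  expect_false(has_heteroduplex(c("converted", "unconverted")))
  expect_true(has_heteroduplex(c("converted", "heteroduplex")))
  expect_warning(got <- has_heteroduplex(rep("unreadable", 3)), "unreadable")
  expect_false(got)
  # invariant under relabeling unconverted <-> unreadable at other sites
  base <- c("heteroduplex", "unconverted", "unreadable", "unconverted")
  swapped <- c("heteroduplex", "unreadable", "unconverted", "unreadable")
  expect_equal(has_heteroduplex(base), has_heteroduplex(swapped))
})

test_that("score_tracts scores per tract and excludes ambiguous recombinants", {
  tr <- sim_tracts(40, ladder = lad5, seed = 5)
  scored <- score_tracts(tr, lad5)
  expect_equal(nrow(scored), length(unique(tr$tract_id)))
  expect_true(all(scored$min_bp <= scored$max_bp))
  expect_true(all(scored$length_class %in% c("short", "long")))
  # flag two tracts ambiguous: they drop from the scored output
  amb_ids <- unique(tr$tract_id)[1:2]
  tr$ambiguous <- tr$tract_id %in% amb_ids
  expect_warning(scored2 <- score_tracts(tr, lad5), "2 ambiguous")
  expect_equal(nrow(scored2), nrow(scored) - 2)
})

test_that("tract tables round-trip through the wide call-code format", {
  wide <- data.frame(
    tract_id = c("t1", "t2"), recombinant_class = c("NCO", "CO"),
    window = c("T22_34", "T10_22"),
    `12` = c("1", "H"), `112` = c("0", "1"), `209` = c("N", "1"),
    `348` = c("0", "0"), `460` = c("0", "0"), check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(wide, path)
  long <- read_tracts(path, lad5)
  expect_equal(nrow(long), 10)
  expect_equal(long$call[long$tract_id == "t1"],
               c("converted", "unconverted", "unreadable", "unconverted",
                 "unconverted"))
  scored <- score_tracts(long, lad5)
  expect_equal(scored$length_class[scored$tract_id == "t1"], "short")
  expect_equal(scored$min_bp[scored$tract_id == "t2"], 198L)
  expect_true(scored$heteroduplex[scored$tract_id == "t2"])
  # unknown codes rejected
  wide$`12`[1] <- "X"
  readr::write_tsv(wide, path)
  expect_error(read_tracts(path, lad5), "unknown call code")
})

test_that("short-tract summaries reproduce the interhomolog-window contrast", {
  # 28 short of 29 tracts: 96.6%, Wilson CI 82.8-99.4%
  ci <- wilson_ci(28, 29)
  expect_equal(round(100 * ci$estimate, 1), 96.6)
  expect_equal(round(100 * ci$conf_low, 1), 82.8)
  expect_equal(round(100 * ci$conf_high, 1), 99.4)
  scored <- tibble::tibble(
    tract_id = sprintf("t%02d", 1:29), recombinant_class = "NCO",
    window = "T22_34", length_class = c(rep("short", 28), "long"))
  ref <- tibble::tibble(
    tract_id = sprintf("r%02d", 1:66), recombinant_class = "NCO",
    window = "T22_34", length_class = c(rep("short", 49), rep("long", 17)))
  s <- tract_summary(scored, ref)
  expect_equal(round(100 * s$estimate, 1), 96.6)
  expect_equal(s$p_value,
               compare_proportions(28, 29, 49, 66)$p_value)
  # all-short vs all-short: p = 1
  allshort <- dplyr::mutate(scored, length_class = "short")
  expect_equal(tract_summary(allshort, allshort)$p_value, 1)
  expect_error(tract_summary(scored[0, ], ref), "nonempty")
  expect_error(
    tract_summary(scored, dplyr::mutate(ref, recombinant_class = "CO")),
    "single recombinant class")
})
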