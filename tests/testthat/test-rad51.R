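test_that("position normalization maps pachytene landmarks to 0 and 1", {
  expect_equal(normalize_positions(c(10, 40), tz_end = 10, pachytene_end = 40),
               c(0, 1))
  expect_equal(normalize_positions(25, 10, 40), 0.5)
  # a transition zone a quarter of pachytene length starts at -0.25
  expect_equal(normalize_positions(2.5, 10, 40), -0.25)
  expect_error(normalize_positions(5, 10, 10), "degenerate")
  expect_error(normalize_positions(5, 10, 8), "degenerate")
})

test_that("per-germline normalization joins landmarks and validates ordering", {
  nuclei <- tibble::tibble(germline_id = c("g1", "g1", "g2"),
                           raw_position = c(10, 40, 35), foci = c(1L, 2L, 0L))
  lm <- tibble::tibble(germline_id = c("g1", "g2"),
                       tz_start = c(2.5, 5), tz_end = c(10, 15),
                       pachytene_end = c(40, 55))
  out <- normalize_germline(nuclei, lm)
  expect_equal(out$norm_position, c(0, 1, 0.5))
  expect_error(normalize_germline(
    dplyr::mutate(nuclei, germline_id = "g9"), lm), "absent")
  bad_lm <- dplyr::mutate(lm, tz_end = c(1, 15))
  expect_error(normalize_germline(nuclei, bad_lm), "ordering")
})

test_that("foci assign to the nearest qualifying nucleus surface", {
  nuc <- tibble::tibble(nucleus_id = 1:2, x = c(0, 10), y = 0, z = 0,
                        radius = 2)
  foc <- tibble::tibble(x = c(0, 2.3, 2.5, 10, 5.9), y = 0, z = 0)
  out <- assign_foci(foc, nuc)
  # center (distance 0) and 0.3 um outside count; 0.5 um outside does not;
  # 5.9 is 3.9 from nucleus 1's surface and 2.1 from nucleus 2's: neither
  expect_equal(out$foci, c(2L, 1L))
  # every focus counted at most once: totals bounded by focus count
  expect_lte(sum(out$foci), nrow(foc))
  expect_error(assign_foci(foc, nuc[0, ]), "empty nucleus")
  expect_error(assign_foci(foc, dplyr::mutate(nuc, radius = 0)), "radii")
})

test_that("focus assignment matches the exhaustive pairwise oracle on random scenes", {
  set.seed(19)
  for (rep in 1:10) {
    nuc <- tibble::tibble(
      nucleus_id = 1:8,
      x = runif(8, 0, 20), y = runif(8, 0, 20), z = runif(8, 0, 5),
      radius = runif(8, 1, 2.5))
    foc <- tibble::tibble(x = runif(40, 0, 20), y = runif(40, 0, 20),
                          z = runif(40, 0, 5))
    expect_equal(assign_foci(foc, nuc)$foci, oracle_assign_foci(foc, nuc))
  }
})

test_that("ties between equidistant nuclei resolve to the lowest nucleus id", {
  nuc <- tibble::tibble(nucleus_id = c(2L, 1L), x = c(0, 6), y = 0, z = 0,
                        radius = 1)
  # focus at x = 3: surface distance 2 to both -> not counted (over threshold)
  # with threshold 2.5 it qualifies for both; nucleus 1 (at x = 6) wins
  out <- assign_foci(tibble::tibble(x = 3, y = 0, z = 0), nuc,
                     threshold = 2.5)
  expect_equal(out$foci[out$nucleus_id == 1], 1L)
  expect_equal(out$foci[out$nucleus_id == 2], 0L)
})

test_that("stage bins are left-open right-closed and tile (-0.25, 1]", {
  bins <- stage_bins()
  expect_equal(bins$lower[-1], bins$upper[-nrow(bins)])
  got <- assign_stage_bin(c(-0.25 + 1e-9, 0, 1e-9, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(as.character(got),
               c("TZ", "TZ", "EP", "EP", "EMP", "MP", "MLP", "LP"))
  expect_true(is.na(assign_stage_bin(-0.3)))
  expect_true(is.na(assign_stage_bin(1.1)))
})

test_that("sliding windows equal the naive filter-and-average oracle", {
  nuclei <- sim_germline(250, function(p) 2 + 3 * (p > 0.5), seed = 23)
  got <- sliding_window_profile(nuclei)
  ref <- oracle_sliding_window(nuclei)
  expect_equal(got$center, ref$center)
  expect_equal(got$mean_foci, ref$mean_foci)
  expect_equal(got$sem, ref$sem)
  expect_equal(got$n, ref$n)
  # invariant under input order
  shuffled <- nuclei[sample(nrow(nuclei)), ]
  expect_equal(sliding_window_profile(shuffled), got)
})

test_that("sliding windows handle constant, sparse and empty inputs", {
  const <- tibble::tibble(norm_position = runif(50, -0.2, 1), foci = 3L)
  prof <- sliding_window_profile(const)
  expect_true(all(prof$mean_foci == 3))
  expect_true(all(prof$sem == 0))
  # a single nucleus: only windows covering it report, with n = 1 and sem 0
  single <- tibble::tibble(norm_position = 0.5, foci = 7L)
  prof1 <- sliding_window_profile(single)
  expect_true(all(abs(prof1$center - 0.5) <= 0.05 + 1e-9))
  expect_true(all(prof1$n == 1 & prof1$sem == 0))
  empty <- sliding_window_profile(tibble::tibble(norm_position = numeric(),
                                                 foci = integer()))
  expect_equal(nrow(empty), 0)
  expect_error(sliding_window_profile(const, width = 0), "width")
})

test_that("nuclei within the profiled span partition exactly across stage bins", {
  nuclei <- sim_germline(300, seed = 29)
  bins <- assign_stage_bin(nuclei$norm_position)
  inside <- nuclei$norm_position > -0.25 & nuclei$norm_position <= 1
  expect_equal(sum(table(bins)), sum(inside))
})

test_that("Mann-Whitney p agrees with wilcox.test in both regimes", {
  # untied small samples: exact enumeration vs wilcox exact
  set.seed(37)
  for (i in 1:10) {
    x <- sample(seq(1, 200), 6)
    y <- sample(seq(201, 400), 7)
    expect_equal(mann_whitney_u(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  # tied large samples: tie-corrected normal approximation
  for (i in 1:10) {
    x <- rpois(30, 3)
    y <- rpois(25, 4)
    expect_equal(mann_whitney_u(x, y),
                 suppressWarnings(stats::wilcox.test(
                   x, y, exact = FALSE, correct = FALSE)$p.value),
                 tolerance = 1e-10)
  }
  # identical samples
  expect_equal(mann_whitney_u(rep(2, 12), rep(2, 15)), 1)
  expect_error(mann_whitney_u(numeric(), 1:3), "nonempty")
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  set.seed(41)
  for (i in 1:50) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p))
    # monotone in p, never below raw, never above Bonferroni
    expect_true(all(diff(adj[order(p)]) >= 0))
    expect_true(all(adj >= p))
    expect_true(all(adj <= pmin(1, length(p) * p) + 1e-12))
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("binned pairwise comparisons form the right Holm families", {
  set.seed(43)
  nuclei <- dplyr::bind_rows(lapply(c("wt", "smc5", "brc1", "dbl"),
    function(g) sim_germline(120, seed = match(g, c("wt", "smc5", "brc1", "dbl")),
                             genotype = g)))
  res <- compare_foci_by_bin(nuclei)
  # 4 genotypes -> 6 pairs per bin, 6 bins
  expect_equal(nrow(res), 36)
  expect_equal(unname(table(res$bin)), rep(6L, 6), ignore_attr = TRUE)
  # adjusted p within each bin reproduces Holm on that bin's raw ps
  for (b in unique(res$bin)) {
    sub <- res[res$bin == b & !is.na(res$p_value), ]
    expect_equal(sub$p_adjusted, holm_adjust(sub$p_value))
  }
  # identical genotypes give adjusted p = 1
  same <- dplyr::bind_rows(
    dplyr::mutate(sim_germline(60, seed = 5), genotype = "a"),
    dplyr::mutate(sim_germline(60, seed = 5), genotype = "b"))
  res_same <- compare_foci_by_bin(same)
  expect_true(all(res_same$p_adjusted == 1, na.rm = TRUE))
  # a genotype empty in a bin is reported missing
  sparse <- dplyr::bind_rows(
    sim_germline(80, seed = 6, genotype = "a"),
    dplyr::filter(sim_germline(80, seed = 7, genotype = "b"),
                  norm_position > 0))
  res_sparse <- compare_foci_by_bin(sparse)
  expect_true(is.na(res_sparse$p_value[res_sparse$bin == "TZ"]))
  expect_error(compare_foci_by_bin(sim_germline(10, seed = 8)), "two genotypes")
})
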