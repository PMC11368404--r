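#' Normalize germline positions to pachytene length
#'
#' Linearized gonad-axis positions are mapped affinely so that the beginning
#' of pachytene (= end of the transition zone) is 0 and the end of pachytene
#' is 1: `(raw - tz_end) / (pachytene_end - tz_end)`. Transition-zone nuclei
#' map to negative positions.
#'
#' @param raw_position Numeric vector of positions along the gonad axis
#'   (any consistent unit).
#' @param tz_end Axis position of the end of the transition zone
#'   (= pachytene start).
#' @param pachytene_end Axis position of the end of pachytene; must exceed
#'   `tz_end`.
#' @return Numeric vector of normalized positions.
#' @export
#' @examples
#' normalize_positions(c(5, 10, 25, 40), tz_end = 10, pachytene_end = 40)
normalize_positions <- function(raw_position, tz_end, pachytene_end) {
  if (!is.finite(tz_end) || !is.finite(pachytene_end) ||
      pachytene_end <= tz_end) {
    abort("degenerate landmarks: `pachytene_end` must exceed `tz_end`.")
  }
  (raw_position - tz_end) / (pachytene_end - tz_end)
}

#' Normalize a nucleus table against per-germline landmarks
#'
#' @param nuclei Tibble with `germline_id`, `raw_position`, `foci`.
#' @param landmarks Tibble with `germline_id`, `tz_start`, `tz_end`,
#'   `pachytene_end` (each germline's own axis landmarks).
#' @return `nuclei` with an added `norm_position` column.
#' @export
normalize_germline <- function(nuclei, landmarks) {
  nuclei <- as_tibble(nuclei)
  landmarks <- as_tibble(landmarks)
  needed <- c("germline_id", "tz_start", "tz_end", "pachytene_end")
  missing_cols <- setdiff(needed, names(landmarks))
  if (length(missing_cols) > 0) {
    abort(paste0("landmarks missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- with(landmarks, !(tz_start < tz_end & tz_end < pachytene_end))
  if (any(bad)) {
    abort(paste0("landmark ordering violated (need tz_start < tz_end < ",
                 "pachytene_end) for germline(s): ",
                 paste(landmarks$germline_id[bad], collapse = ", ")))
  }
  joined <- left_join(nuclei, landmarks, by = "germline_id")
  if (any(is.na(joined$tz_end))) {
    abort("nuclei reference germline_id(s) absent from the landmark table.")
  }
  joined %>%
    mutate(norm_position = normalize_positions_vec(
      .data$raw_position, .data$tz_end, .data$pachytene_end)) %>%
    select(all_of(names(nuclei)), "norm_position")
}

# vectorized over per-row landmarks (validated upstream)
normalize_positions_vec <- function(raw, tz_end, pachytene_end) {
  (raw - tz_end) / (pachytene_end - tz_end)
}

#' Count foci per nucleus from a 3D scene
#'
#' Each focus is counted toward the nearest nucleus whose surface lies
#' within `threshold` micrometers. Nuclei are modeled as spheres; the
#' distance from a focus to a nucleus surface is
#' `max(0, ||focus - center|| - radius)` (a focus inside the nucleus is at
#' distance 0). A focus within threshold of several nuclei is assigned to
#' the nearest one only (ties broken toward the lowest nucleus identifier),
#' so every focus is counted at most once.
#'
#' @param foci Tibble of focus coordinates: `x`, `y`, `z` (micrometers).
#' @param nuclei Tibble of nuclei: `nucleus_id`, `x`, `y`, `z`, `radius`.
#' @param threshold Maximum surface distance in micrometers, default 0.4.
#' @return `nuclei` with an added integer `foci` count column.
#' @export
assign_foci <- function(foci, nuclei, threshold = 0.4) {
  nuclei <- as_tibble(nuclei)
  foci <- as_tibble(foci)
  if (nrow(nuclei) == 0) abort("empty nucleus set.")
  if (any(nuclei$radius <= 0)) abort("nucleus radii must be > 0.")
  nuclei <- arrange(nuclei, .data$nucleus_id)
  counts <- integer(nrow(nuclei))
  if (nrow(foci) > 0) {
    for (i in seq_len(nrow(foci))) {
      d_centre <- sqrt((nuclei$x - foci$x[i])^2 +
                       (nuclei$y - foci$y[i])^2 +
                       (nuclei$z - foci$z[i])^2)
      d_surface <- pmax(0, d_centre - nuclei$radius)
      j <- which(d_surface <= threshold)
      if (length(j) > 0) {
        best <- j[which.min(d_surface[j])]  # ties: lowest id (sorted order)
        counts[best] <- counts[best] + 1L
      }
    }
  }
  mutate(nuclei, foci = counts)
}

#' Stage bins along the normalized germline axis
#'
#' Six meiotic stage bins tiling (-0.25, 1]: transition zone (TZ), early
#' pachytene (EP), early/mid (EMP), mid (MP), mid/late (MLP) and late
#' pachytene (LP). Bins are half-open on the left and closed on the right,
#' so position 0 falls in TZ and position 1 in LP.
#'
#' @return A tibble with `bin` (factor), `lower`, `upper`.
#' @export
stage_bins <- function() {
  tibble(
    bin = factor(c("TZ", "EP", "EMP", "MP", "MLP", "LP"),
                 levels = c("TZ", "EP", "EMP", "MP", "MLP", "LP")),
    lower = c(-0.25, 0, 0.2, 0.4, 0.6, 0.8),
    upper = c(0, 0.2, 0.4, 0.6, 0.8, 1)
  )
}

#' Assign normalized positions to stage bins
#'
#' @param norm_position Numeric vector of normalized positions.
#' @param bins Bin definition from [stage_bins()].
#' @return Factor of bin labels; `NA` outside (-0.25, 1].
#' @export
assign_stage_bin <- function(norm_position, bins = stage_bins()) {
  cut(norm_position, breaks = c(bins$lower[1], bins$upper),
      labels = levels(bins$bin), right = TRUE)
}

#' Sliding-window focus profile along the germline
#'
#' Mean RAD-51 foci per nucleus in overlapping windows along the normalized
#' axis: windows of `width` position units advance by `step` units, centred
#' at `span[1] + width/2 + k * step` for every k keeping the window inside
#' `span`. Window membership uses the closed interval
#' `[centre - width/2, centre + width/2]`. Windows containing no nucleus are
#' omitted.
#'
#' @param nuclei Tibble with `norm_position` and `foci`.
#' @param width Window width in position units, default 0.1.
#' @param step Step size in position units, default 0.01.
#' @param span Numeric length-2 axis span, default `c(-0.25, 1)`.
#' @return A tibble: `center`, `mean_foci`, `sem` (sample SD / sqrt(n); 0
#'   when n = 1), `n`.
#' @export
sliding_window_profile <- function(nuclei, width = 0.1, step = 0.01,
                                   span = c(-0.25, 1)) {
  if (width <= 0 || step <= 0) abort("`width` and `step` must be > 0.")
  nuclei <- as_tibble(nuclei)
  eps <- 1e-9
  centers <- seq(span[1] + width / 2, span[2] - width / 2 + eps, by = step)
  if (nrow(nuclei) == 0) {
    return(tibble(center = numeric(), mean_foci = numeric(),
                  sem = numeric(), n = integer()))
  }
  purrr::map_dfr(centers, function(ct) {
    inside <- nuclei$foci[nuclei$norm_position >= ct - width / 2 - eps &
                          nuclei$norm_position <= ct + width / 2 + eps]
    n <- length(inside)
    if (n == 0) return(NULL)
    tibble(center = ct, mean_foci = mean(inside),
           sem = if (n > 1) sd(inside) / sqrt(n) else 0, n = n)
  })
}

#' Two-sided Mann-Whitney U test for focus counts
#'
#' Exact enumeration of all group assignments when the combined sample size
#' is at most 20 (focus counts are heavily tied, so the exact p is a
#' permutation p on the tie-averaged ranks: the proportion of assignments
#' with |U - E[U]| at least as large as observed). Larger samples use the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param x,y Numeric vectors of per-nucleus focus counts.
#' @param exact_max Combined size at or below which the exact enumeration is
#'   used, default 20.
#' @return The two-sided p-value.
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be nonempty.")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    rank_sums <- colSums(matrix(r[idx], nrow = n1))
    u_all <- rank_sums - n1 * (n1 + 1) / 2
    mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) return(1)
    z <- (u_obs - mu) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }
}

#' Holm-Bonferroni step-down adjustment
#'
#' Sort the m p-values ascending; the i-th smallest becomes
#' `max_{j <= i} min(1, (m - j + 1) p_(j))`; results return in the original
#' order. Delegates to [stats::p.adjust()] after validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
#' @examples
#' holm_adjust(c(0.01, 0.04))  # 0.02, 0.04
holm_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "holm")
}

#' Pairwise focus-count comparisons within stage bins
#'
#' For each stage bin, runs a two-sided Mann-Whitney U test on per-nucleus
#' focus counts for every pair of genotypes, then applies Holm-Bonferroni
#' within the bin across the pairs (family size = number of testable
#' pairs in the bin). A pair with an empty group in a bin is reported with
#' missing p-values and excluded from the Holm family.
#'
#' @param nuclei Tibble with `genotype`, `norm_position`, `foci`.
#' @param bins Bin definitions from [stage_bins()].
#' @param exact_max Passed to [mann_whitney_u()].
#' @return A tibble: `bin`, `genotype1`, `genotype2`, `n1`, `n2`,
#'   `p_value`, `p_adjusted`.
#' @export
compare_foci_by_bin <- function(nuclei, bins = stage_bins(), exact_max = 20) {
  nuclei <- as_tibble(nuclei)
  genotypes <- sort(unique(as.character(nuclei$genotype)))
  if (length(genotypes) < 2) abort("need at least two genotypes to compare.")
  nuclei$bin <- assign_stage_bin(nuclei$norm_position, bins)
  pairs <- combn(genotypes, 2)
  purrr::map_dfr(levels(bins$bin), function(b) {
    sub <- filter(nuclei, !is.na(.data$bin) & .data$bin == b)
    res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      g1 <- sub$foci[sub$genotype == pairs[1, j]]
      g2 <- sub$foci[sub$genotype == pairs[2, j]]
      tibble(
        bin = b, genotype1 = pairs[1, j], genotype2 = pairs[2, j],
        n1 = length(g1), n2 = length(g2),
        p_value = if (length(g1) > 0 && length(g2) > 0) {
          mann_whitney_u(g1, g2, exact_max = exact_max)
        } else NA_real_
      )
    })
    ok <- !is.na(res$p_value)
    res$p_adjusted <- NA_real_
    res$p_adjusted[ok] <- holm_adjust(res$p_value[ok])
    res
  }) %>%
    mutate(bin = factor(.data$bin, levels = levels(bins$bin)))
}
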