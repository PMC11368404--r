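#' Posterior radiosensitivity ratio ("gamma")
#'
#' For each irradiated group, gamma is the per-draw ratio of its mean
#' viability parameter phi to that of the matching unirradiated (0 Rads)
#' group with the same genotype/window (and mating status), paired by draw
#' index — the generated-quantities convention. A gamma of 1 means
#' irradiation had no effect on brood viability; 0 means irradiation
#' sterilized the group.
#'
#' @param fit A `brood_fit` from [fit_brood_model()].
#' @param conf_level Credible mass for the central interval, default 0.95.
#' @return A tibble of class `gamma_estimates`: one row per irradiated
#'   group, with `median`, `conf_low`, `conf_high` and a `draws` list-column
#'   of the per-draw ratios.
#' @export
gamma_posterior <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "brood_fit"))
  key_cols <- fit$key_cols
  base_cols <- setdiff(key_cols, "dose_rads")
  alpha <- (1 - conf_level) / 2

  draws <- arrange(fit$draws, across(all_of(c(key_cols, "chain", "iter"))))
  ref <- draws %>%
    filter(.data$dose_rads == 0) %>%
    select(all_of(base_cols), "chain", "iter", phi0 = "phi")
  irr <- filter(draws, .data$dose_rads > 0)
  if (nrow(irr) == 0) abort("no irradiated (dose_rads > 0) group in the fit.")
  joined <- left_join(irr, ref, by = c(base_cols, "chain", "iter"))
  if (any(is.na(joined$phi0))) {
    abort("missing matching 0-Rads group for at least one irradiated group.")
  }
  out <- joined %>%
    mutate(gamma = .data$phi / .data$phi0) %>%
    group_by(across(all_of(key_cols))) %>%
    summarise(
      median = stats::median(.data$gamma),
      conf_low = stats::quantile(.data$gamma, alpha, names = FALSE),
      conf_high = stats::quantile(.data$gamma, 1 - alpha, names = FALSE),
      draws = list(.data$gamma),
      .groups = "drop"
    )
  class(out) <- c("gamma_estimates", class(out))
  out
}

#' Do two gamma credible intervals overlap?
#'
#' The comparison rule for radiosensitivity between genotypes: two
#' groups are called indistinguishable when their 95% credible intervals
#' intersect.
#'
#' @param a,b One-row slices of a [gamma_posterior()] result (or any objects
#'   with `conf_low` / `conf_high`).
#' @return Logical scalar.
#' @export
gamma_interval_overlap <- function(a, b) {
  stopifnot(!is.null(a$conf_low), !is.null(b$conf_low))
  a$conf_low[1] <= b$conf_high[1] && b$conf_low[1] <= a$conf_high[1]
}

#' Pairwise gamma interval overlaps across genotypes
#'
#' @param gammas A [gamma_posterior()] tibble.
#' @return A tibble of genotype pairs per (window, dose) with an `overlap`
#'   logical column.
#' @export
gamma_overlap_pairs <- function(gammas) {
  split_cols <- intersect(c("window", "dose_rads", "mated"), names(gammas))
  gammas %>%
    group_by(across(all_of(split_cols))) %>%
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) return(tibble())
      idx <- combn(nrow(g), 2)
      tibble(
        genotype1 = g$genotype[idx[1, ]],
        genotype2 = g$genotype[idx[2, ]],
        overlap = vapply(seq_len(ncol(idx)), function(j) {
          gamma_interval_overlap(g[idx[1, j], ], g[idx[2, j], ])
        }, logical(1))
      )
    }) %>%
    ungroup()
}

#' Posterior-predictive simulation of brood viabilities
#'
#' Simulates the expected brood viability of `n_sim` parent hermaphrodites
#' per group: for each simulated parent, a brood size is drawn from a
#' Poisson with rate equal to the group's mean observed brood size, a
#' (phi, lambda) pair is sampled from the group's posterior draws, a hatch
#' probability p from Beta(lambda phi, lambda (1 - phi)), and hatched
#' progeny from Binomial(brood size, p). Zero-brood parents are retained
#' with viability recorded as missing.
#'
#' @param fit A `brood_fit`.
#' @param n_sim Simulated hermaphrodites per group, default 1500.
#' @param seed Integer seed.
#' @param mean_broods Optional tibble of group keys plus `mean_brood`;
#'   defaults to the observed group means in the fitted data.
#' @return A tibble: group keys, `sim_id`, `brood_size`, `hatched`,
#'   `viability` (NA at brood size 0).
#' @export
posterior_predictive_sim <- function(fit, n_sim = 1500, seed = 1,
                                     mean_broods = NULL) {
  stopifnot(inherits(fit, "brood_fit"))
  if (n_sim < 1) abort("`n_sim` must be >= 1.")
  key_cols <- fit$key_cols
  if (is.null(mean_broods)) {
    mean_broods <- fit$data %>%
      group_by(across(all_of(key_cols))) %>%
      summarise(mean_brood = mean(.data$brood_size), .groups = "drop")
  }
  groups <- left_join(fit$groups, mean_broods, by = key_cols)
  if (any(is.na(groups$mean_brood))) {
    abort("`mean_broods` is missing at least one fitted group.")
  }
  with_stream(seed, "posterior_predictive_sim", {
    purrr::map_dfr(seq_len(nrow(groups)), function(i) {
      grp <- groups[i, , drop = FALSE]
      gd <- left_join(grp[, key_cols, drop = FALSE], fit$draws, by = key_cols)
      pick <- sample.int(nrow(gd), n_sim, replace = TRUE)
      brood <- rpois(n_sim, grp$mean_brood)
      p <- rbeta(n_sim, gd$lambda[pick] * gd$phi[pick],
                 gd$lambda[pick] * (1 - gd$phi[pick]))
      hatched <- rbinom(n_sim, brood, p)
      tibble(
        grp[rep(1, n_sim), key_cols, drop = FALSE],
        sim_id = seq_len(n_sim),
        brood_size = brood,
        hatched = hatched,
        viability = ifelse(brood > 0, hatched / brood, NA_real_)
      )
    })
  })
}
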