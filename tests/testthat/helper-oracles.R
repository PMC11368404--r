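# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from its definition by direct enumeration, never by calling the
# implementation under test.

# two-sided Fisher p by direct hypergeometric enumeration over the table
# support, point-probability criterion with relative tolerance 1e-7
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Holm step-down applied literally to its definition
oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[ord[i]])
    running_max <- max(running_max, val)
    adj[ord[i]] <- running_max
  }
  adj
}

# maximal junction microhomology by direct string comparison over all m
oracle_microhomology <- function(ref, s, e) {
  if (s == e) return(0L)
  best <- 0L
  for (m in seq_len(s)) {
    left <- substr(ref, s - m + 1, s)        # 0-based [s-m, s)
    right <- substr(ref, e - m + 1, e)       # 0-based [e-m, e)
    if (identical(left, right)) best <- m else break
  }
  as.integer(best)
}

# minimum tract length by scanning all pairs of converted positions
oracle_min_tract <- function(calls, ladder) {
  conv <- ladder[calls %in% c("converted", "heteroduplex")]
  if (length(conv) == 0) return(NA_integer_)
  best <- 1L
  for (i in seq_along(conv)) {
    for (j in seq_along(conv)) {
      best <- max(best, abs(conv[j] - conv[i]) + 1L)
    }
  }
  as.integer(best)
}

# naive sliding-window profile: explicit loop + subset + mean
oracle_sliding_window <- function(nuclei, width = 0.1, step = 0.01,
                                  span = c(-0.25, 1)) {
  centers <- seq(span[1] + width / 2, span[2] - width / 2 + 1e-9, by = step)
  out <- NULL
  for (ct in centers) {
    v <- nuclei$foci[nuclei$norm_position >= ct - width / 2 - 1e-9 &
                     nuclei$norm_position <= ct + width / 2 + 1e-9]
    if (length(v) == 0) next
    out <- rbind(out, data.frame(
      center = ct, mean_foci = mean(v),
      sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
      n = length(v)))
  }
  out
}

# per-focus nearest-qualifying-nucleus assignment by exhaustive pairwise scan
oracle_assign_foci <- function(foci, nuclei, threshold = 0.4) {
  nuclei <- nuclei[order(nuclei$nucleus_id), ]
  counts <- integer(nrow(nuclei))
  for (i in seq_len(nrow(foci))) {
    best_j <- NA
    best_d <- Inf
    for (j in seq_len(nrow(nuclei))) {
      d <- sqrt(sum((c(foci$x[i], foci$y[i], foci$z[i]) -
                     c(nuclei$x[j], nuclei$y[j], nuclei$z[j]))^2))
      d_surf <- max(0, d - nuclei$radius[j])
      if (d_surf <= threshold && d_surf < best_d) {
        best_d <- d_surf
        best_j <- j
      }
    }
    if (!is.na(best_j)) counts[best_j] <- counts[best_j] + 1L
  }
  counts
}

# a small wild-type-like progeny fixture whose per-window scored-recombinant
# totals are exactly 28/25/22/15, split over two plates per window
progeny_fixture <- function(totals = c(T10_22 = 28, T22_34 = 25,
                                       T34_46 = 22, T46_58 = 15),
                            genotype = "wild_type") {
  rows <- lapply(names(totals), function(w) {
    tot <- totals[[w]]
    nco <- c(ceiling(tot * 0.6), floor(tot * 0.3))
    rem <- tot - sum(nco)
    co <- c(rem - min(2, rem), min(2, rem))
    data.frame(
      genotype = genotype, replicate = c("r1", "r2"),
      parent_id = paste0(w, c("_p1", "_p2")), window = w,
      NCO_recombinant = nco, CO_recombinant = co, mutant = 0L,
      undetermined_recombinant = c(1L, 0L), nonrecombinant = c(40L, 35L),
      dead_egg = c(2L, 1L), unfertilized = c(1L, 0L)
    )
  })
  do.call(rbind, rows)
}

# minimal hand-built brood_fit with fixed posterior draws, for exactness
# tests of the gamma machinery
fake_brood_fit <- function(phi_by_dose, lambda = 50, n_draws = 100) {
  key_cols <- c("genotype", "window", "dose_rads")
  draws <- do.call(rbind, lapply(names(phi_by_dose), function(d) {
    data.frame(genotype = "g", window = "T22_34", dose_rads = as.numeric(d),
               chain = 1L, iter = seq_len(n_draws),
               phi = phi_by_dose[[d]], lambda = lambda)
  }))
  draws <- tibble::as_tibble(draws)
  groups <- dplyr::distinct(draws, genotype, window, dose_rads)
  structure(list(draws = draws, groups = groups, key_cols = key_cols,
                 data = NULL, converged = TRUE),
            class = "brood_fit")
}
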