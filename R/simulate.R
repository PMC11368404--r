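#' Default per-window phenotype class rates for simulated progeny
#'
#' Plausible synthetic per-window class probabilities for a reverse
#' time-course progeny assay (these rates are illustrative defaults, not
#' measured values): recombinants are rare, crossovers a minority of
#' recombinants, and most progeny hatch as nonrecombinant.
#'
#' @return Tibble with `window`, `class`, `prob`; probabilities sum to 1
#'   within each window.
#' @export
default_class_rates <- function() {
  tidyr::expand_grid(
    window = window_levels(),
    tibble(
      class = progeny_classes(),
      prob = c(0.012, 0.004, 0.001, 0.003, 0.90, 0.05, 0.03)
    )
  )
}

#' Simulate a per-parent progeny count table
#'
#' Per parent and window, a brood size is drawn from Poisson(`mean_brood`)
#' and allocated to phenotype classes by a multinomial with the window's
#' class probabilities — the shape of the assays' per-plate source data.
#'
#' @param class_rates Tibble `window`, `class`, `prob`; per-window
#'   probabilities must sum to 1 (tolerance 1e-9).
#' @param n_parents Parents (plates) per window, default 20.
#' @param mean_brood Mean progeny per parent per window, default 60.
#' @param seed Integer seed (the generator draws from its own named stream).
#' @param genotype,replicate Identifiers stamped on every row.
#' @return A wide progeny tibble passing [validate_progeny()].
#' @export
#' @examples
#' sim_progeny(n_parents = 3, seed = 1)
sim_progeny <- function(class_rates = default_class_rates(), n_parents = 20,
                        mean_brood = 60, seed = 1,
                        genotype = "simulated", replicate = "r1") {
  class_rates <- as_tibble(class_rates)
  sums <- class_rates %>%
    group_by(.data$window) %>%
    summarise(s = sum(.data$prob), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-9)) {
    abort("class probabilities must sum to 1 within each window.")
  }
  with_stream(seed, "sim_progeny", {
    purrr::map_dfr(unique(class_rates$window), function(w) {
      probs <- class_rates %>% filter(.data$window == w)
      probs <- probs$prob[match(progeny_classes(), probs$class)]
      broods <- rpois(n_parents, mean_brood)
      counts <- vapply(broods, function(b) {
        as.integer(stats::rmultinom(1, b, probs))
      }, integer(length(progeny_classes())))
      out <- as_tibble(t(counts), .name_repair = "minimal")
      names(out) <- progeny_classes()
      tibble(genotype = genotype, replicate = replicate,
             parent_id = sprintf("%s_p%02d", w, seq_len(n_parents)),
             window = factor(w, levels = window_levels()), out)
    })
  })
}

#' Simulate conversion tract call tables
#'
#' Each recombinant's true conversion tract is anchored at the Mos1 excision
#' site (position 0) and extends 3' for a length drawn from
#' `tract_len_dist`; ladder positions inside the tract are called converted,
#' positions beyond it unconverted, and each converted call flips to
#' heteroduplex with probability `het_rate`. Draws whose tract covers no
#' ladder position are not recombinants at the scored locus; they are
#' dropped and counted in the `n_nonrecombinant` attribute.
#'
#' @param n Number of tracts to draw.
#' @param ladder Polymorphism ladder positions.
#' @param class_mix Named probabilities for `NCO` / `CO` classes.
#' @param tract_len_dist A function `n -> lengths (bp)` or a single number
#'   for a degenerate (fixed) length.
#' @param het_rate Per-converted-site heteroduplex probability, default 0.05.
#' @param window_probs Named probabilities over window labels.
#' @param seed Integer seed.
#' @return Long tract tibble (columns `tract_id`, `recombinant_class`,
#'   `window`, `position`, `call`) ready for [score_tracts()], with
#'   attribute `n_nonrecombinant`.
#' @export
sim_tracts <- function(n, ladder = polymorphism_ladder(),
                       class_mix = c(NCO = 0.7, CO = 0.3),
                       tract_len_dist = function(n) rlnorm(n, log(60), 1),
                       het_rate = 0.05,
                       window_probs = c(T10_22 = 0.25, T22_34 = 0.25,
                                        T34_46 = 0.25, T46_58 = 0.25),
                       seed = 1) {
  if (is.numeric(tract_len_dist)) {
    fixed <- tract_len_dist
    tract_len_dist <- function(n) rep(fixed, n)
  }
  if (abs(sum(class_mix) - 1) > 1e-9) abort("`class_mix` must sum to 1.")
  with_stream(seed, "sim_tracts", {
    lens <- tract_len_dist(n)
    if (any(!is.finite(lens) | lens < 0)) abort("tract lengths must be finite and >= 0.")
    cls <- sample(names(class_mix), n, replace = TRUE, prob = class_mix)
    wins <- sample(names(window_probs), n, replace = TRUE, prob = window_probs)
    rows <- purrr::map(seq_len(n), function(i) {
      converted <- ladder <= lens[i]
      if (!any(converted)) return(NULL)
      call <- ifelse(converted, "converted", "unconverted")
      flip <- converted & runif(length(ladder)) < het_rate
      call[flip] <- "heteroduplex"
      tibble(tract_id = sprintf("t%04d", i), recombinant_class = cls[i],
             window = wins[i], position = ladder, call = call)
    })
    kept <- purrr::compact(rows)
    out <- bind_rows(kept)
    attr(out, "n_nonrecombinant") <- n - length(kept)
    out
  })
}

#' Simulate hermaphrodite brood viability records
#'
#' Generates the model's own data-generating process per hermaphrodite:
#' brood size ~ Poisson(`mean_brood`), hatch probability
#' p ~ Beta(lambda phi, lambda (1 - phi)), hatched ~ Binomial(brood, p).
#' The default 15 hermaphrodites per condition matches the brood-scoring
#' design (three replicates of five).
#'
#' @param groups Tibble with one row per condition: `genotype`, `window`,
#'   `dose_rads`, `phi` in (0,1), `lambda` > 0, `mean_brood`, and
#'   optionally `n_herm` (default 15) and `mated`.
#' @param seed Integer seed.
#' @param mean_unfertilized Poisson mean for the recorded-but-unused
#'   unfertilized oocyte count, default 5.
#' @return A brood record tibble passing [validate_broods()].
#' @export
#' @examples
#' sim_brood(tibble::tibble(genotype = "wt", window = "T22_34",
#'   dose_rads = 0, phi = 0.9, lambda = 50, mean_brood = 200), seed = 1)
sim_brood <- function(groups, seed = 1, mean_unfertilized = 5) {
  groups <- as_tibble(groups)
  if (!"n_herm" %in% names(groups)) groups$n_herm <- 15L
  if (any(groups$phi <= 0 | groups$phi >= 1)) abort("`phi` must lie in (0, 1).")
  if (any(groups$lambda <= 0)) abort("`lambda` must be > 0.")
  key_cols <- intersect(c("genotype", "mated", "window", "dose_rads"),
                        names(groups))
  with_stream(seed, "sim_brood", {
    purrr::map_dfr(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      nh <- g$n_herm
      brood <- rpois(nh, g$mean_brood)
      p <- rbeta(nh, g$lambda * g$phi, g$lambda * (1 - g$phi))
      hatched <- rbinom(nh, brood, p)
      tibble(
        g[rep(1, nh), key_cols, drop = FALSE],
        parent_id = sprintf("h%02d", seq_len(nh)),
        hatched = hatched,
        dead_eggs = brood - hatched,
        unfertilized = rpois(nh, mean_unfertilized)
      )
    })
  })
}

#' Simulate a germline nucleus table
#'
#' Nuclei are placed uniformly along the normalized axis (-0.25, 1] and
#' focus counts drawn from Poisson with a position-dependent rate.
#'
#' @param n_nuclei Number of nuclei.
#' @param rate_fn Function mapping normalized position to a Poisson focus
#'   rate (vectorized, must be >= 0).
#' @param seed Integer seed.
#' @param genotype,germline_id Identifiers stamped on every row.
#' @return Tibble with `genotype`, `germline_id`, `norm_position`, `foci`.
#' @export
sim_germline <- function(n_nuclei, rate_fn = function(pos) rep(2, length(pos)),
                         seed = 1, genotype = "simulated",
                         germline_id = "g1") {
  with_stream(seed, "sim_germline", {
    pos <- runif(n_nuclei, -0.25, 1)
    rates <- rate_fn(pos)
    if (any(!is.finite(rates) | rates < 0)) {
      abort("`rate_fn` must return finite non-negative rates.")
    }
    tibble(genotype = genotype, germline_id = germline_id,
           norm_position = pos, foci = rpois(n_nuclei, rates))
  })
}

#' Simulate deletion junctions with planted microhomology
#'
#' Constructs random reference sequences in which a deletion of `del_size`
#' bp carries exactly `mh_len` bp of junction microhomology: the `mh_len`
#' bases flanking both junction sides are forced equal and the next base
#' outward is forced unequal. Requires `del_size > mh_len` (a microhomology
#' at least as long as the deletion would force flank periodicity that can
#' raise the realized microhomology above the requested value) and
#' `mh_len + del_size + 2 <= ref_len`.
#'
#' @param n Number of events.
#' @param ref_len Reference length in bp, default 30.
#' @param del_size Deletion size in bp.
#' @param mh_len Planted junction microhomology in bp.
#' @param seed Integer seed.
#' @return Tibble with `ref_seq`, `del_start`, `del_end`, `insertion_seq`
#'   (empty), `planted_mh`.
#' @export
sim_junctions <- function(n, ref_len = 30, del_size = 5, mh_len = 2,
                          seed = 1) {
  if (mh_len < 0 || del_size < 1) abort("need `del_size` >= 1, `mh_len` >= 0.")
  if (del_size <= mh_len) {
    abort("infeasible geometry: `del_size` must exceed `mh_len`.")
  }
  if (mh_len + del_size + 2 > ref_len) {
    abort("infeasible geometry: need mh_len + del_size + 2 <= ref_len.")
  }
  bases <- c("A", "C", "G", "T")
  with_stream(seed, "sim_junctions", {
    purrr::map_dfr(seq_len(n), function(i) {
      chars <- sample(bases, ref_len, replace = TRUE)
      # deletion start: leave room for mh_len + 1 flank bases on the left
      s <- sample((mh_len + 1):(ref_len - del_size - 1), 1)
      e <- s + del_size
      if (mh_len > 0) {
        chars[(e - mh_len + 1):e] <- chars[(s - mh_len + 1):s]
      }
      # force a mismatch one base beyond the planted microhomology
      left <- s - mh_len
      right <- e - mh_len
      chars[right] <- sample(setdiff(bases, chars[left]), 1)
      tibble(ref_seq = paste(chars, collapse = ""),
             del_start = s, del_end = e,
             insertion_seq = "", planted_mh = as.integer(mh_len))
    })
  })
}
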