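#' Default polymorphism ladder for the ICR assay locus
#'
#' The assay locus carries polymorphisms from 12 bp to 567 bp 3' of the Mos1
#' excision site (position 0 = excision site). The 12 and 567 bp endpoints
#' are fixed; the interior positions shipped here are plausible synthetic
#' defaults (the true interior spacing is not needed by any classification
#' rule, which depend only on position 12 and the 198 bp threshold).
#'
#' @param positions Strictly increasing bp offsets; first must be 12.
#' @return An integer vector of ladder positions.
#' @export
polymorphism_ladder <- function(positions = c(12, 112, 209, 348, 460, 567)) {
  if (any(diff(positions) <= 0)) abort("ladder positions must be strictly increasing.")
  if (positions[1] != 12) {
    warn("non-default ladder: first position is not the canonical 12 bp site")
  }
  as.integer(positions)
}

tract_call_levels <- function() c("converted", "unconverted", "heteroduplex", "unreadable")

# positions (bp) of calls counting as converted for tract extent:
# heteroduplex counts as converted (heteroduplex points are plotted inside
# tract spans), unreadable is non-informative.
converted_positions <- function(calls, positions) {
  positions[calls %in% c("converted", "heteroduplex")]
}

#' Minimum and maximum conversion tract length of one recombinant
#'
#' The minimum tract is the distance from the most proximal to the most
#' distal converted polymorphism, inclusive of both: `distal - proximal + 1`,
#' so conversion at a single site yields 1 bp. The maximum tract extends the
#' minimum tract to the nearest flanking unconverted polymorphisms on both
#' sides (the excision site, position 0, bounds the proximal side; one past
#' the ladder end bounds the distal side). Heteroduplex calls count as
#' converted for extent; unreadable calls are non-informative.
#'
#' @param calls Character vector of per-position calls in
#'   `c("converted", "unconverted", "heteroduplex", "unreadable")`.
#' @param ladder Ladder positions, same length as `calls`.
#' @return A tibble with `min_bp` and `max_bp`.
#' @export
#' @examples
#' tract_lengths(c("converted", "unconverted"), polymorphism_ladder(c(12, 209)))
tract_lengths <- function(calls, ladder = polymorphism_ladder()) {
  stopifnot(length(calls) == length(ladder))
  bad <- setdiff(unique(calls), tract_call_levels())
  if (length(bad) > 0) abort(paste0("unknown call(s): ", paste(bad, collapse = ", ")))
  conv <- converted_positions(calls, ladder)
  if (length(conv) == 0) {
    abort("no converted positions: tract length undefined for a nonrecombinant.")
  }
  prox <- min(conv)
  dist <- max(conv)
  min_bp <- dist - prox + 1

  unconv <- ladder[calls == "unconverted"]
  left_bound <- if (any(unconv < prox)) max(unconv[unconv < prox]) else 0
  right_bound <- if (any(unconv > dist)) min(unconv[unconv > dist]) else max(ladder) + 1
  max_bp <- right_bound - left_bound - 1
  tibble(min_bp = as.integer(min_bp), max_bp = as.integer(max_bp))
}

#' Classify a noncrossover conversion tract as short or long
#'
#' A noncrossover tract is "short" when sequence conversion is found only at
#' the most proximal polymorphism, 12 bp downstream of the excision site.
#'
#' @inheritParams tract_lengths
#' @param recombinant_class Must be `"NCO"`.
#' @return `"short"` or `"long"`.
#' @export
classify_nco <- function(calls, ladder = polymorphism_ladder(),
                         recombinant_class = "NCO") {
  if (!identical(recombinant_class, "NCO")) {
    abort("classify_nco() applies to NCO tracts only; use classify_co() for crossovers.")
  }
  conv <- converted_positions(calls, ladder)
  if (length(conv) == 0) abort("no converted positions in tract.")
  if (length(conv) == 1 && conv == ladder[1]) "short" else "long"
}

#' Classify a crossover conversion tract as short or long
#'
#' Short crossover tracts are those with minimum tract length <= 198 bp, the
#' median minimum crossover tract length in a wild-type background (the
#' threshold is inclusive).
#'
#' @inheritParams tract_lengths
#' @param recombinant_class Must be `"CO"`.
#' @param threshold_bp Length threshold, default 198.
#' @return `"short"` or `"long"`.
#' @export
classify_co <- function(calls, ladder = polymorphism_ladder(),
                        recombinant_class = "CO", threshold_bp = 198) {
  if (!identical(recombinant_class, "CO")) {
    abort("classify_co() applies to CO tracts only; use classify_nco() for noncrossovers.")
  }
  if (tract_lengths(calls, ladder)$min_bp <= threshold_bp) "short" else "long"
}

#' Does a tract contain heteroduplex DNA?
#'
#' Heteroduplex (unresolved mismatched duplex, seen as two prominent peaks at
#' a known polymorphism in the chromatogram) is flagged when any position
#' carries a heteroduplex call. An all-unreadable tract returns `FALSE` with
#' a data-quality warning.
#'
#' @param calls Character vector of per-position calls.
#' @return Logical scalar.
#' @export
has_heteroduplex <- function(calls) {
  if (length(calls) > 0 && all(calls == "unreadable")) {
    warn("all positions unreadable: heteroduplex status uninformative")
  }
  any(calls == "heteroduplex")
}

#' Score a table of conversion tracts
#'
#' Takes a long tract table (one row per tract x ladder position) and
#' returns one row per tract with lengths, heteroduplex flag and the
#' short/long classification appropriate to its recombinant class. Tracts
#' flagged `ambiguous` (two distinguishable repair products) are excluded
#' from scoring, as are rows with no converted position.
#'
#' @param tracts Tibble with columns `tract_id`, `recombinant_class`
#'   (`"NCO"`/`"CO"`), `window`, `position`, `call`, and optionally
#'   `ambiguous` (logical).
#' @param ladder Ladder positions; every tract must carry a call at each.
#' @return One row per scored tract: `tract_id`, `recombinant_class`,
#'   `window`, `interhomolog`, `min_bp`, `max_bp`, `heteroduplex`,
#'   `length_class`.
#' @export
score_tracts <- function(tracts, ladder = polymorphism_ladder()) {
  tracts <- as_tibble(tracts)
  needed <- c("tract_id", "recombinant_class", "window", "position", "call")
  missing_cols <- setdiff(needed, names(tracts))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"ambiguous" %in% names(tracts)) tracts$ambiguous <- FALSE
  n_amb <- tracts %>% filter(.data$ambiguous) %>% distinct(.data$tract_id) %>% nrow()
  if (n_amb > 0) {
    warn(sprintf("%d ambiguous tract(s) excluded from scoring", n_amb))
  }
  tracts %>%
    filter(!.data$ambiguous) %>%
    arrange(.data$tract_id, .data$position) %>%
    group_by(.data$tract_id, .data$recombinant_class, .data$window) %>%
    summarise(
      scored = list({
        stopifnot(identical(as.integer(.data$position), ladder))
        tract_lengths(.data$call, ladder)
      }),
      heteroduplex = has_heteroduplex(.data$call),
      length_class = if (.data$recombinant_class[1] == "NCO") {
        classify_nco(.data$call, ladder)
      } else {
        classify_co(.data$call, ladder, recombinant_class = "CO")
      },
      .groups = "drop"
    ) %>%
    tidyr::unnest("scored") %>%
    mutate(interhomolog = is_interhomolog(.data$window),
           .after = "window")
}

#' Summarise short-tract frequency and compare with a reference
#'
#' The fraction of short tracts among all scored tracts of one class, with a
#' Wilson interval, and a two-sided Fisher exact test against a reference
#' set's short/long counts.
#'
#' @param scored Scored tract tibble from [score_tracts()], already filtered
#'   to one recombinant class and window group.
#' @param reference Scored tract tibble for the comparison group (same
#'   class/window filtering).
#' @inheritParams wilson_ci
#' @return A one-row tibble: `n_short`, `n_tracts`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`.
#' @export
tract_summary <- function(scored, reference, conf_level = 0.95) {
  if (nrow(scored) == 0 || nrow(reference) == 0) {
    abort("both tract collections must be nonempty.")
  }
  cls <- unique(c(scored$recombinant_class, reference$recombinant_class))
  if (length(cls) != 1) {
    abort("tract_summary() compares collections of a single recombinant class.")
  }
  k1 <- sum(scored$length_class == "short")
  n1 <- nrow(scored)
  k0 <- sum(reference$length_class == "short")
  n0 <- nrow(reference)
  cmp <- compare_proportions(k1, n1, k0, n0, conf_level = conf_level)
  tibble(
    n_short = k1, n_tracts = n1,
    estimate = k1 / n1,
    conf_low = cmp$estimates$conf_low[1],
    conf_high = cmp$estimates$conf_high[1],
    p_value = cmp$p_value
  )
}

#' Read a tract call table
#'
#' One row per recombinant; call columns named by ladder position hold codes
#' `1` (converted), `0` (unconverted), `H` (heteroduplex), `N` (unreadable).
#'
#' @param path Delimited text file.
#' @param ladder Expected ladder positions.
#' @return Long tibble suitable for [score_tracts()].
#' @export
read_tracts <- function(path, ladder = polymorphism_ladder()) {
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = "c"))
  pos_cols <- as.character(ladder)
  missing_cols <- setdiff(c("tract_id", "recombinant_class", "window", pos_cols),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  code_map <- c(`1` = "converted", `0` = "unconverted",
                H = "heteroduplex", N = "unreadable")
  long <- raw %>%
    tidyr::pivot_longer(all_of(pos_cols), names_to = "position",
                        values_to = "code") %>%
    mutate(position = as.integer(.data$position))
  bad <- setdiff(unique(long$code), names(code_map))
  if (length(bad) > 0) {
    abort(paste0("unknown call code(s): ", paste(bad, collapse = ", ")))
  }
  long %>%
    mutate(call = unname(code_map[.data$code])) %>%
    select(-"code")
}
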