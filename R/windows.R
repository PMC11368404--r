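#' The canonical reverse-time-course timepoint windows
#'
#' The heat-shock reverse time course scores progeny laid in four 12-hour
#' windows spanning 10--58 hr post heat shock. Progeny laid 22--58 hr derive
#' from oocytes that were in leptotene--mid-pachytene at the time of the heat
#' shock (the "interhomolog window", when the homolog is available as a repair
#' template); progeny laid 10--22 hr derive from late-pachytene--diplotene
#' oocytes (the "non-interhomolog window").
#'
#' @return A tibble with columns `window` (factor `T10_22`, `T22_34`,
#'   `T34_46`, `T46_58`), `start_hr`, `end_hr` and `interhomolog` (logical).
#' @export
#' @examples
#' timepoint_windows()
timepoint_windows <- function() {
  tibble(
    window = factor(c("T10_22", "T22_34", "T34_46", "T46_58"),
                    levels = window_levels()),
    start_hr = c(10, 22, 34, 46),
    end_hr = c(22, 34, 46, 58),
    interhomolog = c(FALSE, TRUE, TRUE, TRUE)
  )
}

window_levels <- function() c("T10_22", "T22_34", "T34_46", "T46_58")

#' Assign hours post heat shock to a timepoint window
#'
#' Windows are half-open `[start, end)`: a brood transfer at hour 22 begins
#' the next window, matching the transfer-at-22/34/46, discard-at-58 protocol.
#'
#' @param hours_post_heat_shock Numeric vector of laying times, hours post
#'   heat shock. All values must fall in `[10, 58)`.
#' @param windows Window definition table, as from [timepoint_windows()].
#' @return A factor of window labels, same length as the input.
#' @export
#' @examples
#' assign_window(c(15, 22, 57.9))
assign_window <- function(hours_post_heat_shock, windows = timepoint_windows()) {
  h <- hours_post_heat_shock
  if (!is.numeric(h) || any(!is.finite(h))) {
    abort("`hours_post_heat_shock` must be finite numeric.")
  }
  lo <- min(windows$start_hr)
  hi <- max(windows$end_hr)
  bad <- h < lo | h >= hi
  if (any(bad)) {
    abort(sprintf(
      "hours post heat shock outside the assay span [%g, %g): %s",
      lo, hi, paste(format(h[bad]), collapse = ", ")
    ))
  }
  idx <- findInterval(h, windows$start_hr)
  factor(as.character(windows$window)[idx], levels = levels(windows$window))
}

#' Is a timepoint window inside the interhomolog window?
#'
#' The interhomolog window comprises the 22--58 hr post-heat-shock laying
#' windows; the 10--22 hr window is the non-interhomolog window.
#'
#' @param window Character or factor vector of window labels.
#' @return Logical vector.
#' @export
#' @examples
#' is_interhomolog(c("T10_22", "T22_34"))
is_interhomolog <- function(window) {
  w <- as.character(window)
  defs <- timepoint_windows()
  unknown <- setdiff(unique(w), as.character(defs$window))
  if (length(unknown) > 0) {
    abort(paste0("unknown window label(s): ", paste(unknown, collapse = ", ")))
  }
  defs$interhomolog[match(w, as.character(defs$window))]
}
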