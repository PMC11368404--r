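#' Junction microhomology of a deletion
#'
#' The largest m >= 0 such that the m bases immediately left of the deletion
#' start equal the m bases immediately left of the deletion end, i.e. the
#' same sequence abuts both sides of the junction, so the deletion could have
#' been joined by annealing at m complementary nucleotides. Exact-match
#' identity only (no mismatches).
#'
#' @param ref_seq Reference nucleotide string around the excision site.
#' @param del_start,del_end Half-open deletion interval `[del_start, del_end)`
#'   in 0-based coordinates of `ref_seq`. An empty interval returns 0.
#' @return Integer microhomology length in bp.
#' @export
#' @examples
#' junction_microhomology("GCATCCGATGG", 4, 9)  # 2 ("AT" flanks both junctions)
junction_microhomology <- function(ref_seq, del_start, del_end) {
  stopifnot(is.character(ref_seq), length(ref_seq) == 1L)
  len <- nchar(ref_seq)
  if (del_start < 0 || del_end > len || del_start > del_end) {
    abort(sprintf("deletion [%d, %d) out of bounds for a %d nt reference.",
                  del_start, del_end, len))
  }
  if (del_start == del_end) return(0L)
  chars <- strsplit(ref_seq, "")[[1]]
  m_max <- del_start  # both compared blocks end at or before their junctions
  m <- 0L
  while (m < m_max &&
         chars[del_start - m] == chars[del_end - m]) {
    m <- m + 1L
  }
  m
}

#' Is an insertion templated from nearby reference sequence?
#'
#' Flags insertions of at least `min_len` bases whose sequence (or reverse
#' complement) occurs in the reference, the hallmark of polymerase
#' theta-templated synthesis. Short insertions match by chance and are never
#' flagged.
#'
#' @param ref_seq Reference nucleotide string.
#' @param insertion_seq Inserted sequence (possibly empty).
#' @param min_len Minimum insertion length to consider, default 3.
#' @return Logical scalar.
#' @export
is_templated_insertion <- function(ref_seq, insertion_seq, min_len = 3) {
  if (is.na(insertion_seq) || nchar(insertion_seq) < min_len) return(FALSE)
  revcomp <- function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  grepl(insertion_seq, ref_seq, fixed = TRUE) ||
    grepl(revcomp(insertion_seq), ref_seq, fixed = TRUE)
}

#' Classify mutation events by end-joining signature
#'
#' Scores each mutagenic repair product for the signatures of theta-mediated
#' end joining (TMEJ): a small (< 50 bp) deletion bearing one or more
#' complementary nucleotides on both ends of the deletion (junction
#' microhomology), or a templated insertion.
#'
#' @param events Tibble with columns `ref_seq`, `del_start`, `del_end`
#'   (0-based half-open), `insertion_seq` (empty string or `NA` for none),
#'   and optionally `templated` (logical; computed via
#'   [is_templated_insertion()] when absent).
#' @param max_del_bp Deletion size bound for the TMEJ size rule, default 50
#'   (exclusive).
#' @return The input with added `del_bp`, `size_bp` (deletion plus insertion
#'   length), `mh_len`, `templated` and `tmej_like`.
#' @export
classify_mutations <- function(events, max_del_bp = 50) {
  events <- as_tibble(events)
  needed <- c("ref_seq", "del_start", "del_end", "insertion_seq")
  missing_cols <- setdiff(needed, names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  ins <- ifelse(is.na(events$insertion_seq), "", events$insertion_seq)
  if (!"templated" %in% names(events)) {
    events$templated <- purrr::map2_lgl(events$ref_seq, ins,
                                        is_templated_insertion)
  }
  events %>%
    mutate(
      mh_len = purrr::pmap_int(
        list(.data$ref_seq, .data$del_start, .data$del_end),
        junction_microhomology
      ),
      del_bp = as.integer(.data$del_end - .data$del_start),
      size_bp = .data$del_bp + nchar(ins),
      tmej_like = .data$del_bp < max_del_bp &
        (.data$mh_len >= 1 | .data$templated)
    )
}
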