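#' Phenotype classes scored in the progeny assays
#'
#' The ICR and IH assays classify each F1 progeny into mutually exclusive
#' classes. `undetermined_recombinant` holds progeny whose recombinant class
#' could not be resolved (unsequenced GFP+ in the ICR assay, "undetermined
#' non-Unc" in the IH assay); they are retained in totals but excluded from
#' recombinant-class denominators.
#'
#' @return Character vector of class names.
#' @export
progeny_classes <- function() {
  c("NCO_recombinant", "CO_recombinant", "mutant",
    "undetermined_recombinant", "nonrecombinant", "dead_egg", "unfertilized")
}

#' Default column schema for progeny tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names of an input file. Override entries to read tables with different
#' headers.
#'
#' @param ... Named overrides, e.g. `genotype = "strain"`.
#' @return Named character vector mapping canonical name -> file column.
#' @export
progeny_schema <- function(...) {
  schema <- c(
    genotype = "genotype", replicate = "replicate", parent_id = "parent_id",
    window = "window",
    setNames(progeny_classes(), progeny_classes())
  )
  overrides <- c(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(schema))
    if (length(unknown) > 0) {
      abort(paste0("unknown schema field(s): ", paste(unknown, collapse = ", ")))
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

#' Read and validate a progeny count table
#'
#' Reads a delimited (comma or tab) per-parent, per-window table of phenotype
#' class counts, validates it, and returns a tibble in canonical column
#' order. The atomic unit is one plate (one `parent_id`), matching how the
#' assays' source data are recorded; plates hosting several parents are still
#' one row.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Column mapping from [progeny_schema()].
#' @return A tibble with columns `genotype`, `replicate`, `parent_id`,
#'   `window` (factor) and one integer column per phenotype class.
#' @export
read_progeny <- function(path, schema = progeny_schema()) {
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  validate_progeny(raw, schema)
}

#' Validate an in-memory progeny table
#'
#' @param data A data frame of per-plate counts.
#' @inheritParams read_progeny
#' @return The validated tibble, canonical names, counts as integers.
#' @export
validate_progeny <- function(data, schema = progeny_schema()) {
  data <- as_tibble(data)
  missing_cols <- setdiff(unname(schema), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- data[, unname(schema)]
  names(out) <- names(schema)

  problems <- character()
  for (cls in progeny_classes()) {
    v <- suppressWarnings(as.numeric(out[[cls]]))
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf(
        "column '%s': invalid count in row(s) %s",
        schema[[cls]], paste(bad, collapse = ", ")
      ))
    }
  }
  w <- as.character(out$window)
  bad_w <- which(!w %in% window_levels())
  if (length(bad_w) > 0) {
    problems <- c(problems, sprintf(
      "column '%s': unknown window label in row(s) %s",
      schema[["window"]], paste(bad_w, collapse = ", ")
    ))
  }
  if (length(problems) > 0) {
    abort(c("progeny table failed validation:", problems))
  }
  out$window <- factor(w, levels = window_levels())
  out <- mutate(out, across(all_of(progeny_classes()), as.integer))
  out
}

#' Aggregate phenotype class counts over grouping keys
#'
#' Sums the class-count columns within groups (typically genotype and
#' window). Totals are conserved: the grand total over groups equals the
#' grand total over input rows.
#'
#' @param data A validated progeny tibble (see [validate_progeny()]).
#' @param ... Grouping columns, unquoted (e.g. `genotype, window`).
#' @return A tibble of per-group summed class counts plus `total`,
#'   `recombinant` (NCO + CO + undetermined) and `scored_recombinant`
#'   (NCO + CO only, the denominator for crossover proportions).
#' @export
#' @examples
#' tbl <- sim_progeny(n_parents = 4, seed = 1)
#' aggregate_progeny(tbl, genotype, window)
aggregate_progeny <- function(data, ...) {
  keys <- rlang::enquos(...)
  key_names <- vapply(keys, rlang::as_label, character(1))
  unknown <- setdiff(key_names, names(data))
  if (length(unknown) > 0) {
    abort(paste0("unknown grouping key(s): ", paste(unknown, collapse = ", ")))
  }
  data %>%
    group_by(!!!keys) %>%
    summarise(across(all_of(progeny_classes()), sum), .groups = "drop") %>%
    mutate(
      total = rowSums(across(all_of(progeny_classes()))),
      recombinant = .data$NCO_recombinant + .data$CO_recombinant +
        .data$undetermined_recombinant,
      scored_recombinant = .data$NCO_recombinant + .data$CO_recombinant
    )
}

#' Validate a brood viability record table
#'
#' Brood size is defined as hatched + dead eggs; unfertilized oocytes are
#' recorded but never enter the brood size, and viability is
#' hatched / brood size (undefined at brood size 0).
#'
#' @param data Data frame with columns `genotype`, `window`, `dose_rads`,
#'   `hatched`, `dead_eggs`, `unfertilized` and optionally `mated`,
#'   `replicate`, `parent_id`.
#' @return Tibble with added `brood_size` and `viability` (NA when brood
#'   size is 0).
#' @export
validate_broods <- function(data) {
  data <- as_tibble(data)
  needed <- c("genotype", "window", "dose_rads", "hatched", "dead_eggs",
              "unfertilized")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("hatched", "dead_eggs", "unfertilized")) {
    check_count(data[[col]], col)
  }
  if (!all(data$dose_rads %in% c(0, 2500, 5000))) {
    warn("dose_rads contains values other than 0/2500/5000 Rads")
  }
  data %>%
    mutate(
      brood_size = .data$hatched + .data$dead_eggs,
      viability = ifelse(.data$brood_size > 0,
                         .data$hatched / .data$brood_size, NA_real_)
    )
}

#' Validate a sister chromatid exchange (SCE) scoring table
#'
#' @param data Data frame with columns `genotype`, `image_id`, `sce_pairs`,
#'   `scorable_pairs`.
#' @return The validated tibble.
#' @export
validate_sce <- function(data) {
  data <- as_tibble(data)
  needed <- c("genotype", "image_id", "sce_pairs", "scorable_pairs")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check_count(data$sce_pairs, "sce_pairs")
  check_count(data$scorable_pairs, "scorable_pairs")
  if (any(data$sce_pairs > data$scorable_pairs)) {
    abort("sce_pairs exceeds scorable_pairs in at least one row")
  }
  data
}
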