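# Long table -> wide feature tables (time-aware and time-agnostic).

#' @keywords internal
new_feature_table <- function(data, time_aware, filters = character(0),
                              normalization = NA_character_,
                              segments = NULL, formulas = NULL) {
  structure(
    tibble::as_tibble(data),
    time_aware = time_aware,
    filters = filters,
    normalization = normalization,
    segments = segments,
    formulas = formulas,
    class = c("dom_features", class(tibble::tibble()))
  )
}

#' Provenance and structure of a feature table
#'
#' @param ft A feature table from [build_time_aware()] or
#'   [build_time_agnostic()].
#' @return A list with `time_aware`, `filters`, `normalization`, and (for
#'   time-aware tables) the named `segments` vector mapping feature keys to
#'   segment start times and `formulas` mapping feature keys to formula
#'   labels.
#' @export
ft_provenance <- function(ft) {
  stopifnot(inherits(ft, "dom_features"))
  list(
    time_aware = attr(ft, "time_aware"),
    filters = attr(ft, "filters"),
    normalization = attr(ft, "normalization"),
    segments = attr(ft, "segments"),
    formulas = attr(ft, "formulas")
  )
}

#' Feature matrix of a feature table
#'
#' @param ft A feature table.
#' @return Numeric matrix (samples x features) with sample ids as row names.
#' @export
ft_matrix <- function(ft) {
  stopifnot(inherits(ft, "dom_features"))
  m <- as.matrix(ft[, setdiff(names(ft), "sample_id"), drop = FALSE])
  rownames(m) <- ft$sample_id
  m
}

# Rebuild a feature table around a modified matrix, keeping provenance in
# sync and subsetting key maps to the surviving columns.
.ft_update <- function(ft, m, add_filter = NULL, normalization = NULL) {
  prov <- ft_provenance(ft)
  keys <- colnames(m)
  data <- tibble::tibble(sample_id = rownames(m))
  data <- dplyr::bind_cols(data, tibble::as_tibble(m))
  new_feature_table(
    data,
    time_aware = prov$time_aware,
    filters = c(prov$filters, add_filter),
    normalization = normalization %||% prov$normalization,
    segments = if (!is.null(prov$segments)) prov$segments[keys],
    formulas = if (!is.null(prov$formulas)) prov$formulas[keys]
  )
}

.validate_long <- function(long) {
  required <- c("sample_id", "segment_start", "formula", "intensity")
  missing_cols <- setdiff(required, names(long))
  if (length(missing_cols) > 0) {
    abort(paste0("Long table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(long) == 0) {
    abort("Long table is empty.")
  }
  if (any(long$intensity < 0)) {
    abort("Long table contains negative intensities.")
  }
  dup <- duplicated(long[, c("sample_id", "segment_start", "formula")])
  if (any(dup)) {
    abort(sprintf(
      "Long table has %d duplicated (sample, segment, formula) keys, e.g. row %d.",
      sum(dup), which(dup)[1]))
  }
  invisible(long)
}

.feature_key <- function(formula, segment_start) {
  paste0(formula, "@", format(segment_start, trim = TRUE, scientific = FALSE))
}

#' Build the time-aware wide feature table
#'
#' One column per (molecular formula, retention-time segment) combination
#' observed anywhere in the long table (an "MFRT" feature); the entry is
#' the measured intensity, or zero where the combination was not detected
#' in that sample. Columns are ordered lexicographically by formula label
#' and then by segment start time, and rows by sample id, so the table is
#' invariant to the record order of the input.
#'
#' @param long A long table: tibble with columns `sample_id`,
#'   `segment_start` (minutes), `formula` (Hill label), `intensity`.
#' @return A `dom_features` tibble (first column `sample_id`) whose
#'   provenance marks it `time_aware`.
#' @export
build_time_aware <- function(long) {
  .validate_long(long)
  long <- dplyr::arrange(long, .data$formula, .data$segment_start,
                         .data$sample_id)
  keys <- unique(tibble::tibble(
    key = .feature_key(long$formula, long$segment_start),
    formula = long$formula,
    segment = long$segment_start
  ))
  wide <- long |>
    dplyr::mutate(key = .feature_key(.data$formula, .data$segment_start)) |>
    dplyr::select("sample_id", "key", "intensity") |>
    tidyr::pivot_wider(names_from = "key", values_from = "intensity",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  wide <- wide[, c("sample_id", keys$key)]
  new_feature_table(
    wide,
    time_aware = TRUE,
    segments = setNames(keys$segment, keys$key),
    formulas = setNames(keys$formula, keys$key)
  )
}

#' Build the time-agnostic wide feature table
#'
#' One column per distinct molecular formula (an "MF" feature); the entry
#' is the mean of the formula's intensities over the segments in which it
#' was detected for that sample, or zero when the formula is absent from
#' the sample everywhere. Averaging is over detected segments only, not
#' over all segments with zeros counted; a zero entry denotes absence.
#'
#' @inheritParams build_time_aware
#' @param zero_inclusive If `TRUE`, average over all segments present
#'   anywhere for that formula, counting undetected segments as zeros (the
#'   alternative reading of "mean of all intensities"); default `FALSE`.
#' @return A `dom_features` tibble whose provenance marks it time-agnostic.
#' @export
build_time_agnostic <- function(long, zero_inclusive = FALSE) {
  .validate_long(long)
  if (zero_inclusive) {
    seg_count <- long |>
      dplyr::group_by(.data$formula) |>
      dplyr::summarise(n_seg = dplyr::n_distinct(.data$segment_start),
                       .groups = "drop")
    agg <- long |>
      dplyr::group_by(.data$sample_id, .data$formula) |>
      dplyr::summarise(total = sum(.data$intensity), .groups = "drop") |>
      dplyr::left_join(seg_count, by = "formula") |>
      dplyr::mutate(intensity = .data$total / .data$n_seg) |>
      dplyr::select("sample_id", "formula", "intensity")
  } else {
    agg <- long |>
      dplyr::group_by(.data$sample_id, .data$formula) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
  }
  keys <- sort(unique(agg$formula))
  wide <- agg |>
    tidyr::pivot_wider(names_from = "formula", values_from = "intensity",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  wide <- wide[, c("sample_id", keys)]
  new_feature_table(
    wide,
    time_aware = FALSE,
    formulas = setNames(keys, keys)
  )
}

#' Reconstruct a long table from a time-aware feature table
#'
#' Inverse of [build_time_aware()] for unnormalized tables: zero entries
#' are dropped and the (sample, segment, formula) records are re-emitted.
#'
#' @param ft A time-aware `dom_features` table.
#' @return A long-table tibble.
#' @export
feature_table_to_long <- function(ft) {
  prov <- ft_provenance(ft)
  if (!isTRUE(prov$time_aware)) {
    abort("Only time-aware feature tables can be converted back to a long table.")
  }
  m <- ft_matrix(ft)
  nz <- which(m > 0, arr.ind = TRUE)
  keys <- colnames(m)[nz[, 2]]
  tibble::tibble(
    sample_id = rownames(m)[nz[, 1]],
    segment_start = unname(prov$segments[keys]),
    formula = unname(prov$formulas[keys]),
    intensity = m[nz]
  ) |>
    dplyr::arrange(.data$sample_id, .data$formula, .data$segment_start)
}
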