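# Delimited text formats: the long table and wide feature tables.

.long_schema <- c("sample_id", "segment_start_min", "formula", "intensity",
                  "c475", "doc_umol_kg")
.long_optional <- c("longitude", "latitude", "depth", "datetime")

#' Read a long-format LC-FTMS table
#'
#' Reads a tab-separated long table with one row per (sample,
#' retention-time segment, molecular formula) record and per-sample
#' metadata columns. Required columns: `sample_id`, `segment_start_min`,
#' `formula`, `intensity`, `c475`, `doc_umol_kg`; optional: `longitude`,
#' `latitude`, `depth`, `datetime`. Duplicate (sample, segment, formula)
#' keys, negative intensities, unparseable formulas and missing or
#' inconsistent per-sample metadata are rejected with row-numbered errors.
#'
#' @param path Path to a TSV file.
#' @return A list with `long` (tibble: `sample_id`, `segment_start`,
#'   `formula`, `intensity`) and `samples` (tibble: `sample_id`, `c475`,
#'   `doc`, plus any optional metadata).
#' @export
read_long_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  missing_cols <- setdiff(.long_schema, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Long table is missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  .report_rows <- function(idx, what) {
    abort(sprintf("%s in rows: %s%s", what,
                  paste(head(idx, 10), collapse = ", "),
                  if (length(idx) > 10) sprintf(" (and %d more)", length(idx) - 10) else ""))
  }
  dup <- which(duplicated(raw[, c("sample_id", "segment_start_min", "formula")]))
  if (length(dup) > 0) .report_rows(dup, "Duplicated (sample, segment, formula) keys")
  neg <- which(!is.finite(raw$intensity) | raw$intensity < 0)
  if (length(neg) > 0) .report_rows(neg, "Missing or negative intensities")
  na_meta <- which(!is.finite(raw$c475) | !is.finite(raw$doc_umol_kg))
  if (length(na_meta) > 0) .report_rows(na_meta, "Missing C475 or DOC metadata")
  parse_formula(unique(raw$formula))  # errors on invalid labels

  per_sample <- raw |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(n_c475 = dplyr::n_distinct(.data$c475),
                     n_doc = dplyr::n_distinct(.data$doc_umol_kg),
                     .groups = "drop")
  bad <- per_sample$sample_id[per_sample$n_c475 > 1 | per_sample$n_doc > 1]
  if (length(bad) > 0) {
    abort(sprintf("Inconsistent per-sample metadata for sample(s): %s",
                  paste(head(bad, 10), collapse = ", ")))
  }

  samples <- raw |>
    dplyr::distinct(.data$sample_id, .data$c475, .data$doc_umol_kg,
                    dplyr::across(dplyr::any_of(.long_optional))) |>
    dplyr::rename(doc = "doc_umol_kg") |>
    dplyr::arrange(.data$sample_id)
  long <- raw |>
    dplyr::transmute(sample_id = .data$sample_id,
                     segment_start = .data$segment_start_min,
                     formula = .data$formula,
                     intensity = .data$intensity)
  list(long = long, samples = samples)
}

#' Write a long-format LC-FTMS table
#'
#' Serializes a long table plus per-sample metadata to the TSV schema of
#' [read_long_table()]. Writing then reading reproduces the input.
#'
#' @param long Long tibble (`sample_id`, `segment_start`, `formula`,
#'   `intensity`).
#' @param samples Per-sample metadata (`sample_id`, `c475`, `doc`, plus
#'   optional columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(long, samples, path) {
  .validate_long(long)
  keep <- intersect(c("sample_id", "c475", "doc", .long_optional),
                    names(samples))
  out <- long |>
    dplyr::left_join(samples[, keep], by = "sample_id") |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      segment_start_min = .data$segment_start,
      formula = .data$formula,
      intensity = .data$intensity,
      c475 = .data$c475,
      doc_umol_kg = .data$doc,
      dplyr::across(dplyr::any_of(.long_optional))
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a feature table with a provenance header
#'
#' Serializes a wide feature table as TSV preceded by comment lines
#' (`# key: value`) recording its provenance: table format, applied
#' filters and normalization.
#'
#' @param ft A `dom_features` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  prov <- ft_provenance(ft)
  header <- c(
    sprintf("# time_aware: %s", prov$time_aware),
    sprintf("# filters: %s",
            if (length(prov$filters) == 0) "none" else
              paste(prov$filters, collapse = ",")),
    sprintf("# normalization: %s",
            if (is.na(prov$normalization)) "none" else prov$normalization)
  )
  writeLines(header, path)
  readr::write_tsv(tibble::as_tibble(ft), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Path to the TSV file.
#' @return A `dom_features` table with provenance restored (for
#'   time-aware tables, segment assignments are recovered from the
#'   `formula@segment` feature keys).
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- header[startsWith(header, paste0("# ", key, ":"))]
    if (length(ln) == 0) return(NA_character_)
    trimws(sub(paste0("# ", key, ":"), "", ln[1]))
  }
  time_aware <- identical(get_field("time_aware"), "TRUE")
  filters <- get_field("filters")
  filters <- if (is.na(filters) || filters == "none") character(0) else
    strsplit(filters, ",")[[1]]
  normalization <- get_field("normalization")
  if (identical(normalization, "none")) normalization <- NA_character_

  data <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  keys <- setdiff(names(data), "sample_id")
  segments <- formulas <- NULL
  if (time_aware) {
    segments <- setNames(as.numeric(sub("^.*@", "", keys)), keys)
    formulas <- setNames(sub("@.*$", "", keys), keys)
  } else {
    formulas <- setNames(keys, keys)
  }
  new_feature_table(data, time_aware = time_aware, filters = filters,
                    normalization = normalization, segments = segments,
                    formulas = formulas)
}
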