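# Feature elimination and intensity normalizations, plus the target Z-score.

#' The 32 preprocessing combinations
#'
#' Crosses the two wide-table formats, four feature-elimination choices and
#' four normalizations into the full design grid of 2 x 4 x 4 = 32
#' preprocessing combinations.
#'
#' @return A 32-row tibble with columns `table_format` (`"time_aware"`,
#'   `"time_agnostic"`), `elimination` (`"none"`, `"ubiquitous"`,
#'   `"no_low_variance"`, `"both"`) and `normalization` (`"DOC-N"`,
#'   `"SUM"`, `"UBISUM"`, `"ALR"`).
#' @export
preprocess_specs <- function() {
  tidyr::expand_grid(
    table_format = c("time_aware", "time_agnostic"),
    elimination = c("none", "ubiquitous", "no_low_variance", "both"),
    normalization = c("DOC-N", "SUM", "UBISUM", "ALR")
  )
}

.ubiquitous_cols <- function(m) {
  colnames(m)[colSums(m == 0) == 0]
}

#' Keep only ubiquitous features
#'
#' Drops every feature (column) that contains at least one zero entry; the
#' remaining features carry signal in every sample (and, for time-aware
#' tables, in that feature's segment for every sample) and are called
#' ubiquitous.
#'
#' @param ft A `dom_features` table.
#' @return The filtered table, with `"ubiquitous"` appended to its filter
#'   provenance.
#' @export
filter_ubiquitous <- function(ft) {
  m <- ft_matrix(ft)
  keep <- .ubiquitous_cols(m)
  if (length(keep) == 0) {
    abort(paste0("No ubiquitous features remain: every feature has at least ",
                 "one zero. For synthetic data, increase the ubiquitous core."))
  }
  .ft_update(ft, m[, keep, drop = FALSE], add_filter = "ubiquitous")
}

#' Drop low-variance features
#'
#' Drops every feature whose fraction of zero entries is strictly greater
#' than `max_zero_fraction` (default 0.9, i.e. features detected in fewer
#' than 10% of samples); the remaining features are called "no low
#' variance".
#'
#' @param ft A `dom_features` table.
#' @param max_zero_fraction Highest tolerated zero fraction (default 0.9).
#' @return The filtered table with `"no_low_variance"` appended to its
#'   filter provenance.
#' @export
filter_low_variance <- function(ft, max_zero_fraction = 0.9) {
  m <- ft_matrix(ft)
  zero_frac <- colMeans(m == 0)
  keep <- colnames(m)[zero_frac <= max_zero_fraction]
  if (length(keep) == 0) {
    abort("No features remain after low-variance filtering.")
  }
  .ft_update(ft, m[, keep, drop = FALSE], add_filter = "no_low_variance")
}

#' DOC normalization
#'
#' Divides every intensity of a sample by that sample's dissolved organic
#' carbon (DOC) concentration, compensating for differing amounts of
#' organic material across unequalized seawater samples.
#'
#' @param ft A `dom_features` table.
#' @param doc Per-sample DOC in micromol/kg: either a numeric vector named
#'   by sample id, or a data frame with columns `sample_id` and `doc`.
#' @return The normalized table (provenance normalization `"DOC-N"`).
#' @export
normalize_doc <- function(ft, doc) {
  m <- ft_matrix(ft)
  if (is.data.frame(doc)) {
    doc <- setNames(doc$doc, doc$sample_id)
  }
  missing_ids <- setdiff(rownames(m), names(doc))
  if (length(missing_ids) > 0) {
    abort(sprintf("Missing DOC concentration for sample '%s'.", missing_ids[1]))
  }
  d <- doc[rownames(m)]
  bad <- which(!is.finite(d) | d <= 0)
  if (length(bad) > 0) {
    abort(sprintf("Non-positive DOC concentration for sample '%s'.",
                  rownames(m)[bad[1]]))
  }
  .ft_update(ft, m / d, normalization = "DOC-N")
}

# Segment id per column for block-wise normalization: one block per row for
# time-agnostic tables, one block per (row, segment) for time-aware tables
# ("a spectrum" is one retention-time segment's mass spectrum).
.norm_blocks <- function(ft, m) {
  prov <- ft_provenance(ft)
  if (isTRUE(prov$time_aware)) {
    seg <- prov$segments[colnames(m)]
    split(seq_len(ncol(m)), seg)
  } else {
    list(all = seq_len(ncol(m)))
  }
}

.block_normalize <- function(ft, denominator_cols = NULL, label) {
  m <- ft_matrix(ft)
  blocks <- .norm_blocks(ft, m)
  out <- m
  for (bn in names(blocks)) {
    cols <- blocks[[bn]]
    den_cols <- if (is.null(denominator_cols)) {
      cols
    } else {
      intersect(cols, denominator_cols)
    }
    if (length(den_cols) == 0) {
      abort(sprintf(
        "%s normalization failed: no ubiquitous features in segment %s.",
        label, bn))
    }
    den <- rowSums(m[, den_cols, drop = FALSE])
    zero <- which(den == 0)
    if (length(zero) > 0) {
      where <- if (length(blocks) > 1) sprintf(" in segment %s", bn) else ""
      abort(sprintf("%s normalization failed: sample '%s' has zero total intensity%s.",
                    label, rownames(m)[zero[1]], where))
    }
    out[, cols] <- m[, cols, drop = FALSE] / den
  }
  .ft_update(ft, out, normalization = label)
}

#' Sum normalization
#'
#' Divides each intensity by the summed intensity of its spectrum: the
#' whole sample row for time-agnostic tables, or the sample's
#' retention-time segment block for time-aware tables (each segment is one
#' summed mass spectrum).
#'
#' @param ft A `dom_features` table.
#' @return The normalized table (provenance `"SUM"`).
#' @export
normalize_sum <- function(ft) {
  .block_normalize(ft, denominator_cols = NULL, label = "SUM")
}

#' Ubiquitous-sum normalization
#'
#' Like [normalize_sum()], but the denominator sums only over the
#' ubiquitous features (those with no zero entry anywhere in the table),
#' giving a common reference basis across samples that is robust to
#' occasionally detected contaminants. On a table whose features are all
#' ubiquitous this coincides with sum normalization.
#'
#' @param ft A `dom_features` table.
#' @return The normalized table (provenance `"UBISUM"`).
#' @export
normalize_ubisum <- function(ft) {
  m <- ft_matrix(ft)
  ubiq <- .ubiquitous_cols(m)
  if (length(ubiq) == 0) {
    abort("UBISUM normalization requires at least one ubiquitous feature.")
  }
  .block_normalize(ft, denominator_cols = match(ubiq, colnames(m)),
                   label = "UBISUM")
}

#' Additive log-ratio (ALR) transform
#'
#' Compositional transform: every entry becomes the natural logarithm of
#' its ratio to the sample's value of a reference feature, chosen as the
#' ubiquitous feature with the lowest intensity variance across samples
#' (computed on the untransformed table). Zeros are replaced beforehand by
#' one third of the smallest nonzero intensity in the whole table, a
#' standard detection-limit surrogate. The reference column is retained
#' (all zeros after the transform).
#'
#' @param ft A `dom_features` table.
#' @return The transformed table (provenance `"ALR"`); the chosen
#'   reference feature key is stored in the `alr_reference` attribute.
#' @export
alr_transform <- function(ft) {
  m <- ft_matrix(ft)
  ubiq <- .ubiquitous_cols(m)
  if (length(ubiq) == 0) {
    abort("ALR transform requires at least one ubiquitous feature as reference.")
  }
  v <- apply(m[, ubiq, drop = FALSE], 2, var)
  candidates <- sort(ubiq[v == min(v)])
  if (length(candidates) > 1) {
    inform(sprintf(
      "ALR reference tie among %d features; using lexicographically first ('%s').",
      length(candidates), candidates[1]))
  }
  ref <- candidates[1]
  nonzero <- m[m > 0]
  if (length(nonzero) == 0) abort("ALR transform on an all-zero table.")
  repl <- min(nonzero) / 3
  m[m == 0] <- repl
  out <- log(m / m[, ref])
  ft2 <- .ft_update(ft, out, normalization = "ALR")
  attr(ft2, "alr_reference") <- ref
  ft2
}

#' Z-score standardization of the prediction target
#'
#' Centers the fluorescence target at zero and rescales it to units of
#' standard deviations (sample standard deviation, n - 1). Positive
#' standardized values read as terrestrial-leaning, negative as
#' marine-leaning. The mean, standard deviation and original range are
#' retained so predictions can be mapped back to the original intensity
#' scale.
#'
#' @param x Numeric vector of per-sample target values (original scale).
#' @return A list of class `"dom_scaler"` with elements `values`
#'   (standardized target), `mean`, `sd` and `range` (of the original
#'   values).
#' @export
zscore_target <- function(x) {
  if (length(x) < 2) abort("Target standardization needs at least two values.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Target is constant; Z-score standardization is undefined.")
  }
  structure(
    list(values = (x - mean(x)) / s, mean = mean(x), sd = s, range = range(x)),
    class = "dom_scaler"
  )
}

#' Invert the target Z-score
#'
#' @param scaler A `"dom_scaler"` from [zscore_target()].
#' @param z Standardized values.
#' @return Values on the original target scale.
#' @export
inverse_zscore <- function(scaler, z) {
  stopifnot(inherits(scaler, "dom_scaler"))
  z * scaler$sd + scaler$mean
}

#' Apply one preprocessing combination to a long table
#'
#' Runs the pipeline wide-table construction -> feature elimination ->
#' normalization for a single row of [preprocess_specs()]. Elimination
#' happens before normalization, which is what makes sum and
#' ubiquitous-sum normalization coincide on ubiquitous-filtered tables.
#'
#' @param long A long table (see [build_time_aware()]).
#' @param spec A one-row data frame (or list) with `table_format`,
#'   `elimination`, `normalization`.
#' @param samples Per-sample metadata with `sample_id` and `doc` (required
#'   for `"DOC-N"`).
#' @return A preprocessed `dom_features` table.
#' @export
apply_preprocess <- function(long, spec, samples = NULL) {
  fmt <- match.arg(spec$table_format, c("time_aware", "time_agnostic"))
  elim <- match.arg(spec$elimination,
                    c("none", "ubiquitous", "no_low_variance", "both"))
  norm <- match.arg(spec$normalization, c("DOC-N", "SUM", "UBISUM", "ALR"))
  ft <- switch(fmt,
    time_aware = build_time_aware(long),
    time_agnostic = build_time_agnostic(long)
  )
  ft <- switch(elim,
    none = ft,
    ubiquitous = filter_ubiquitous(ft),
    no_low_variance = filter_low_variance(ft),
    both = filter_ubiquitous(filter_low_variance(ft))
  )
  switch(norm,
    `DOC-N` = {
      if (is.null(samples)) abort("DOC-N normalization needs `samples` with a `doc` column.")
      normalize_doc(ft, samples)
    },
    SUM = normalize_sum(ft),
    UBISUM = normalize_ubisum(ft),
    ALR = alr_transform(ft)
  )
}
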