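# CHNOS formula chemistry: parsing, Hill labels, DBE-O, element ratios.

# Monoisotopic masses (Da) of the supported elements.
.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.elements <- names(.element_masses)

#' Parse CHNOS molecular formula strings
#'
#' Parses Hill-notation molecular formula strings over the element set
#' C, H, N, O, S into a tibble of element counts. Dissolved organic matter
#' (DOM) formula assignments from FT-ICR-MS are conventionally restricted to
#' these five elements; any other element symbol (including P) is rejected
#' with an error rather than silently dropped.
#'
#' @param x Character vector of formula strings, e.g. `"C6H12O6"`. An
#'   implicit count of 1 is allowed (`"CH4"`).
#' @param validate If `TRUE` (default), require at least one carbon and one
#'   hydrogen atom, the usual validity floor for assigned DOM formulas.
#'
#' @return A tibble with one row per input and columns `formula` (the
#'   canonical Hill-notation label: C, H, then N, O, S alphabetically),
#'   `C`, `H`, `N`, `O`, `S` (integer counts) and `mass` (monoisotopic
#'   neutral mass in Da).
#'
#' @examples
#' parse_formula(c("C6H12O6", "CH4"))
#' @export
parse_formula <- function(x, validate = TRUE) {
  if (length(x) == 0) {
    abort("`x` must contain at least one formula string.")
  }
  x <- as.character(x)
  counts <- matrix(0L, nrow = length(x), ncol = length(.elements),
                   dimnames = list(NULL, .elements))
  for (i in seq_along(x)) {
    counts[i, ] <- .parse_one_formula(x[[i]])
  }
  if (validate) {
    bad <- which(counts[, "C"] < 1L | counts[, "H"] < 1L)
    if (length(bad) > 0) {
      abort(sprintf(
        "Formula '%s' is invalid: CHNOS formulas must contain at least one C and one H.",
        x[[bad[1]]]
      ))
    }
  }
  tibble::tibble(
    formula = format_formula(tibble::as_tibble(counts)),
    C = unname(counts[, "C"]), H = unname(counts[, "H"]),
    N = unname(counts[, "N"]), O = unname(counts[, "O"]),
    S = unname(counts[, "S"]),
    mass = as.numeric(counts %*% .element_masses)
  )
}

.parse_one_formula <- function(label) {
  if (is.na(label) || !nzchar(trimws(label))) {
    abort("Empty formula string cannot be parsed.")
  }
  label <- trimws(label)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", label, perl = TRUE)[[1]]
  tokens <- regmatches(label, list(m))[[1]]
  if (paste(tokens, collapse = "") != label) {
    leftover <- sub(paste0("^", paste(vapply(tokens, .regex_escape, ""),
                                      collapse = "")), "", label)
    abort(sprintf("Cannot parse formula '%s': unexpected token near '%s'.",
                  label, substr(leftover, 1, 8)))
  }
  out <- setNames(integer(length(.elements)), .elements)
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    if (!elem %in% .elements) {
      abort(sprintf(
        "Cannot parse formula '%s': unknown element symbol '%s' (supported: %s).",
        label, elem, paste(.elements, collapse = ", ")))
    }
    digits <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(digits)) suppressWarnings(as.integer(digits)) else 1L
    if (is.na(n) || n <= 0L) {
      abort(sprintf("Cannot parse formula '%s': element '%s' has count '%s' (must be >= 1).",
                    label, elem, digits))
    }
    if (out[[elem]] > 0L) {
      abort(sprintf("Cannot parse formula '%s': element '%s' appears more than once.",
                    label, elem))
    }
    out[[elem]] <- n
  }
  out
}

.regex_escape <- function(x) gsub("([.\\\\+*?\\[^\\]$(){}=!<>|:#-])", "\\\\\\1", x)

#' Format element counts as canonical Hill-notation labels
#'
#' @param counts A data frame with columns `C`, `H`, `N`, `O`, `S`
#'   (non-negative integer counts), or a named numeric vector.
#' @return Character vector of canonical labels: carbon first, hydrogen
#'   second, remaining elements alphabetically; elements with zero count are
#'   omitted and a count of one is written without a digit.
#' @examples
#' format_formula(data.frame(C = 6, H = 12, N = 0, O = 6, S = 0))
#' @export
format_formula <- function(counts) {
  counts <- .as_count_table(counts)
  vapply(seq_len(nrow(counts)), function(i) {
    parts <- character(0)
    for (el in .elements) {
      n <- counts[[el]][i]
      if (n >= 1) {
        parts <- c(parts, if (n == 1) el else paste0(el, n))
      }
    }
    paste(parts, collapse = "")
  }, character(1))
}

.as_count_table <- function(f) {
  if (is.character(f)) {
    return(parse_formula(f, validate = FALSE))
  }
  if (is.numeric(f) && !is.null(names(f))) {
    f <- tibble::as_tibble(as.list(f))
  }
  if (!is.data.frame(f)) {
    abort("Expected formula strings or a data frame of element counts.")
  }
  f <- tibble::as_tibble(f)
  for (el in .elements) {
    if (!el %in% names(f)) f[[el]] <- 0
  }
  f
}

#' Double-bond equivalents minus oxygen (DBE-O)
#'
#' Computes `DBE - O` with the standard CHNOS ring-and-double-bond
#' equivalent `DBE = 1 + C - H/2 + N/2` (sulfur and oxygen are divalent in
#' this convention and do not contribute to DBE). DBE-O is a common validity
#' criterion for assigned DOM formulas; chemically plausible formulas fall
#' at or below about ten.
#'
#' @param f Character vector of formula labels or a data frame of element
#'   counts (as returned by [parse_formula()]).
#' @return Numeric vector of DBE-O values.
#' @examples
#' dbe_o("C6H6")  # benzene: DBE 4, no oxygen -> 4
#' @export
dbe_o <- function(f) {
  cnt <- .as_count_table(f)
  1 + cnt$C - cnt$H / 2 + cnt$N / 2 - cnt$O
}

#' Element ratio of a (possibly fractional) composition
#'
#' Computes `counts[num] / counts[den]`, e.g. the nitrogen-to-carbon (N/C)
#' or sulfur-to-carbon (S/C) atom ratio used to characterize terrestrial
#' versus marine DOM. Also accepts fractional average compositions such as
#' those produced by [shap_composition()].
#'
#' @param f Formula labels or a data frame of (fractional) element counts.
#' @param num,den Element symbols from `C`, `H`, `N`, `O`, `S`.
#' @return Numeric vector of ratios.
#' @examples
#' element_ratio("C18H21NO9S", "N", "C")
#' @export
element_ratio <- function(f, num, den) {
  num <- match.arg(num, .elements)
  den <- match.arg(den, .elements)
  cnt <- .as_count_table(f)
  if (any(cnt[[den]] == 0)) {
    abort(sprintf("Element ratio undefined: denominator element '%s' has zero count.", den))
  }
  cnt[[num]] / cnt[[den]]
}

#' Filter a formula space by maximum DBE-O
#'
#' Keeps exactly the formulas with `dbe_o(f) <= max_dbe_o`, preserving
#' input order. Used to restrict assigned formulas to the chemically
#' plausible region (default maximum of ten).
#'
#' @param formulas Character vector of labels or a formula tibble.
#' @param max_dbe_o Maximum allowed DBE-O (default 10).
#' @return Object of the same type as `formulas`, subset to passing rows.
#' @examples
#' filter_formula_space(c("C6H6", "C20H10"))
#' @export
filter_formula_space <- function(formulas, max_dbe_o = 10) {
  if (length(formulas) == 0 ||
      (is.data.frame(formulas) && nrow(formulas) == 0)) {
    return(formulas)
  }
  keep <- dbe_o(formulas) <= max_dbe_o
  if (is.data.frame(formulas)) formulas[keep, , drop = FALSE] else formulas[keep]
}
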