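# Seeded generator for LC-FTMS-like long tables with a latent
# terrestrial/marine two end-member mixture and a fluorescence-style target.

#' Configuration for the synthetic LC-FTMS data generator
#'
#' Bundles and validates the knobs of [generate_dataset()]. The defaults
#' emulate the structure of a 95-sample oceanic LC-FTMS molecular formula
#' survey: ten 1-minute retention-time segments starting at 12.3--22.3 min,
#' about 79.3% zero-filled entries in the time-aware wide table, and a
#' fluorescence target (C475) spanning 0.00927--0.0624 intensity units.
#'
#' @param n_samples Number of water samples (default 95).
#' @param n_formulas Number of distinct molecular formulas (default 300; the
#'   real survey carries tens of thousands, scaled down for tractability).
#' @param n_segments Number of retention-time segments (default 10).
#' @param segment_start_times Segment start times in minutes (default 12.3
#'   to 22.3 in 1-minute steps).
#' @param target_zero_fraction Fraction of zero entries in the time-aware
#'   wide table after detection-limit thinning (default 0.793).
#' @param c475_range Range of the fluorescence target on its original,
#'   unitless scale (default `c(0.00927, 0.0624)`).
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   target (default 0.0019, i.e. 3.5% of the default target range,
#'   matching the repeatability of the fluorescence method the target
#'   emulates).
#' @param doc_range Range of dissolved organic carbon concentrations in
#'   micromol/kg (default 50--130, typical of Arctic seawater).
#' @param tau_shape Two Beta shape parameters for the latent terrestrial
#'   fraction tau (default `c(2, 2)`).
#' @param core_fraction Fraction of formulas forming a guaranteed
#'   "ubiquitous core" detected in every sample and segment (default 0.05),
#'   so that ubiquitous-feature operations are well defined.
#' @param thinning Either `"censor"` (remove lowest intensities first,
#'   mimicking detection limits; default) or `"uniform"` (remove entries at
#'   random; useful for property tests).
#' @param seed Integer seed; the whole dataset is deterministic given it.
#'
#' @return A list of class `"dom_config"`.
#' @export
generator_config <- function(n_samples = 95,
                             n_formulas = 300,
                             n_segments = 10,
                             segment_start_times = seq(12.3, by = 1,
                                                       length.out = n_segments),
                             target_zero_fraction = 0.793,
                             c475_range = c(0.00927, 0.0624),
                             noise_sd = 0.0019,
                             doc_range = c(50, 130),
                             tau_shape = c(2, 2),
                             core_fraction = 0.05,
                             thinning = c("censor", "uniform"),
                             seed = 1L) {
  thinning <- match.arg(thinning)
  stopifnot(
    n_samples >= 5,
    n_formulas >= 1,
    n_segments >= 1,
    length(segment_start_times) == n_segments,
    target_zero_fraction >= 0, target_zero_fraction < 1,
    length(c475_range) == 2, c475_range[1] < c475_range[2],
    noise_sd >= 0,
    length(doc_range) == 2, doc_range[1] > 0, doc_range[1] < doc_range[2],
    length(tau_shape) == 2, all(tau_shape > 0),
    core_fraction >= 0, core_fraction < 1
  )
  structure(
    list(
      n_samples = as.integer(n_samples),
      n_formulas = as.integer(n_formulas),
      n_segments = as.integer(n_segments),
      segment_start_times = as.numeric(segment_start_times),
      target_zero_fraction = target_zero_fraction,
      c475_range = as.numeric(c475_range),
      noise_sd = noise_sd,
      doc_range = as.numeric(doc_range),
      tau_shape = as.numeric(tau_shape),
      core_fraction = core_fraction,
      thinning = thinning,
      seed = as.integer(seed)
    ),
    class = "dom_config"
  )
}

#' Generate a random CHNOS formula space
#'
#' Draws `n` distinct CHNOS molecular formulas whose neutral masses lie in
#' `mass_range` and whose DBE-O does not exceed `max_dbe_o`, mirroring the
#' plausibility filter applied to assigned DOM formulas. Hydrogen counts
#' are derived from a sampled integer DBE so every formula has an integer
#' ring-and-double-bond count.
#'
#' @param n Number of distinct formulas.
#' @param seed Integer seed (deterministic output).
#' @param mass_range Neutral mass window in Da (default 150--1000, the
#'   m/z acquisition window of the emulated instrument).
#' @param max_dbe_o Maximum DBE-O (default 10).
#' @return A formula tibble as returned by [parse_formula()].
#' @export
generate_formula_space <- function(n, seed = 1L, mass_range = c(150, 1000),
                                   max_dbe_o = 10) {
  stopifnot(n >= 1, length(mass_range) == 2, mass_range[1] < mass_range[2])
  withr::with_seed(seed, {
    labels <- character(0)
    tries <- 0L
    while (length(labels) < n) {
      tries <- tries + 1L
      if (tries > 200L) {
        abort(sprintf(
          "Could not enumerate %d distinct formulas within mass %g-%g Da and DBE-O <= %g.",
          n, mass_range[1], mass_range[2], max_dbe_o))
      }
      batch <- max(2L * n, 200L)
      C <- sample(4:50, batch, replace = TRUE)
      N <- sample(0:3, batch, replace = TRUE, prob = c(0.55, 0.25, 0.15, 0.05))
      S <- sample(0:2, batch, replace = TRUE, prob = c(0.8, 0.15, 0.05))
      O <- vapply(C, function(ci) sample(0:min(25L, ci), 1L), integer(1))
      d_max <- pmin(C, O + max_dbe_o)
      d <- vapply(d_max, function(dm) sample(0:dm, 1L), integer(1))
      H <- 2L + 2L * C - 2L * d + N
      ok <- H >= 1L
      cand <- tibble::tibble(C = C[ok], H = H[ok], N = N[ok], O = O[ok], S = S[ok])
      cand$mass <- as.numeric(as.matrix(cand[, .elements]) %*% .element_masses)
      cand <- cand[cand$mass >= mass_range[1] & cand$mass <= mass_range[2], ]
      if (nrow(cand) == 0) next
      labels <- unique(c(labels, format_formula(cand)))
    }
    parse_formula(labels[seq_len(n)])
  })
}

#' Generate terrestrial and marine end-member profiles
#'
#' Builds the two latent source profiles the generator mixes: the
#' terrestrial profile up-weights formulas with neutral mass in 200--400 Da
#' and low N/C and S/C ratios, while the marine profile up-weights
#' higher-mass, N- and S-richer formulas. Each formula additionally gets a
#' per-segment chromatographic elution weight (summing to one across
#' segments); a designated ubiquitous core of formulas elutes with positive
#' weight in every segment.
#'
#' @param formulas Formula tibble from [generate_formula_space()].
#' @param seed Integer seed.
#' @param n_segments Number of retention-time segments.
#' @param core_fraction Fraction of formulas assigned to the ubiquitous
#'   core (at least one formula when `core_fraction > 0`).
#' @return A list of class `"dom_end_members"` with elements `profile`
#'   (tibble: `formula`, `terrestrial`, `marine`, `core`), `elution`
#'   (formulas x segments weight matrix) and `core` (core formula labels).
#' @export
generate_end_members <- function(formulas, seed = 1L, n_segments = 10,
                                 core_fraction = 0.05) {
  stopifnot(is.data.frame(formulas), nrow(formulas) >= 1)
  n <- nrow(formulas)
  if (n == 1) {
    warn("Single-formula space: terrestrial and marine profiles are equal up to scale.")
  }
  withr::with_seed(seed, {
    base <- rlnorm(n, meanlog = log(1e4), sdlog = 0.5)
    nc <- formulas$N / formulas$C
    sc <- formulas$S / formulas$C
    in_low_mass <- formulas$mass >= 200 & formulas$mass <= 400
    heavy <- formulas$mass > 400
    terr_aff <- 2 * in_low_mass - 2 * heavy - 8 * nc - 12 * sc
    marine_aff <- 2 * heavy - 2 * in_low_mass + 8 * nc + 12 * sc
    terrestrial <- base * exp(terr_aff + rnorm(n, 0, 0.1))
    marine <- base * exp(marine_aff + rnorm(n, 0, 0.1))

    n_core <- if (core_fraction > 0) max(1L, round(core_fraction * n)) else 0L
    core_idx <- if (n_core > 0) sort(sample.int(n, n_core)) else integer(0)

    elution <- matrix(0, nrow = n, ncol = n_segments)
    for (i in seq_len(n)) {
      if (i %in% core_idx) {
        w <- rgamma(n_segments, shape = 5, rate = 1)
      } else {
        center <- sample.int(n_segments, 1)
        width <- sample(1:2, 1)
        w <- stats::dnorm(seq_len(n_segments), mean = center, sd = width / 1.5)
        w[abs(seq_len(n_segments) - center) > width] <- 0
      }
      elution[i, ] <- w / sum(w)
    }
    rownames(elution) <- formulas$formula

    structure(
      list(
        profile = tibble::tibble(
          formula = formulas$formula,
          terrestrial = terrestrial,
          marine = marine,
          core = seq_len(n) %in% core_idx
        ),
        elution = elution,
        core = formulas$formula[core_idx]
      ),
      class = "dom_end_members"
    )
  })
}

#' Generate a synthetic LC-FTMS long table with metadata
#'
#' Simulates per-sample molecular formula intensity records as a convex
#' mixture of the terrestrial and marine end-member profiles: sample `i`
#' draws a latent terrestrial fraction `tau_i ~ Beta(shape1, shape2)` and
#' its intensity for formula `f` in segment `t` is
#' `(tau_i * terrestrial_f + (1 - tau_i) * marine_f) * elution_{f,t} *
#' scale_i`. Low intensities are then censored (or thinned uniformly) until
#' the time-aware wide table reaches the configured zero fraction; the
#' ubiquitous core and each feature's per-column maximum are never removed,
#' so every sample and feature retains signal. The fluorescence target is
#' linear in `tau` plus Gaussian noise, clipped at zero, and DOC is
#' positively correlated with total sample intensity.
#'
#' @param config A [generator_config()].
#' @return A list of class `"dom_sim"` with elements `long` (tibble:
#'   `sample_id`, `segment_start`, `formula`, `intensity`), `samples`
#'   (tibble: `sample_id`, `c475`, `doc`, and the latent truth `tau`),
#'   `formulas`, `end_members` and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "dom_config"))
  cfg <- config
  fs <- generate_formula_space(cfg$n_formulas, seed = cfg$seed)
  em <- generate_end_members(fs, seed = cfg$seed + 1L,
                             n_segments = cfg$n_segments,
                             core_fraction = cfg$core_fraction)
  withr::with_seed(cfg$seed + 2L, {
    ns <- cfg$n_samples
    tau <- rbeta(ns, cfg$tau_shape[1], cfg$tau_shape[2])
    scale_i <- rlnorm(ns, 0, 0.3)

    # samples x formulas mixture means, then spread over observed segments
    mix <- outer(tau, em$profile$terrestrial) +
      outer(1 - tau, em$profile$marine)          # ns x nf
    obs <- which(em$elution > 0, arr.ind = TRUE)  # (formula, segment) pairs
    pair_formula <- rownames(em$elution)[obs[, 1]]
    pair_segment <- cfg$segment_start_times[obs[, 2]]
    w <- em$elution[obs]
    # cells: ns x n_pairs
    M <- (mix[, obs[, 1], drop = FALSE] *
            matrix(w, nrow = ns, ncol = nrow(obs), byrow = TRUE)) * scale_i

    core_pair <- pair_formula %in% em$core
    protected <- matrix(FALSE, nrow = ns, ncol = nrow(obs))
    protected[, core_pair] <- TRUE
    protected[cbind(max.col(t(M)), seq_len(nrow(obs)))] <- TRUE

    n_cells <- length(M)
    k <- round(cfg$target_zero_fraction * n_cells)
    removable <- which(!protected)
    if (k > length(removable)) {
      abort(sprintf(
        paste0("Infeasible target_zero_fraction %.3f: only %d of %d cells can ",
               "be zeroed without emptying a sample or feature."),
        cfg$target_zero_fraction, length(removable), n_cells))
    }
    if (k > 0) {
      drop_idx <- switch(cfg$thinning,
        censor = removable[order(M[removable])[seq_len(k)]],
        uniform = sample(removable, k)
      )
      M[drop_idx] <- 0
    }

    nz <- which(M > 0, arr.ind = TRUE)
    sample_ids <- sprintf("S%03d", seq_len(ns))
    long <- tibble::tibble(
      sample_id = sample_ids[nz[, 1]],
      segment_start = pair_segment[nz[, 2]],
      formula = pair_formula[nz[, 2]],
      intensity = M[nz]
    ) |>
      dplyr::arrange(.data$sample_id, .data$formula, .data$segment_start)

    c475 <- cfg$c475_range[1] + diff(cfg$c475_range) * tau +
      rnorm(ns, 0, cfg$noise_sd)
    c475 <- pmax(c475, 0)

    total <- rowSums(M)
    z <- if (diff(range(total)) > 0) {
      (total - min(total)) / diff(range(total))
    } else {
      rep(0.5, ns)
    }
    doc <- cfg$doc_range[1] + diff(cfg$doc_range) * (0.7 * z + 0.3 * runif(ns))

    samples <- tibble::tibble(
      sample_id = sample_ids,
      c475 = c475,
      doc = doc,
      tau = tau
    )

    structure(
      list(long = long, samples = samples, formulas = fs,
           end_members = em, config = cfg),
      class = "dom_sim"
    )
  })
}

#' @export
print.dom_sim <- function(x, ...) {
  cat(sprintf(
    "<dom_sim> %d samples, %d formulas, %d segments, %d long-table records\n",
    x$config$n_samples, x$config$n_formulas, x$config$n_segments,
    nrow(x$long)))
  invisible(x)
}
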