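test_that("the preprocessing design crosses formats, eliminations and normalizations", {
  specs <- preprocess_specs()
  expect_equal(nrow(specs), 32)
  expect_equal(nrow(dplyr::distinct(specs)), 32)
  expect_setequal(unique(specs$table_format), c("time_aware", "time_agnostic"))
  expect_setequal(unique(specs$elimination),
                  c("none", "ubiquitous", "no_low_variance", "both"))
  expect_setequal(unique(specs$normalization), c("DOC-N", "SUM", "UBISUM", "ALR"))
})

test_that("ubiquitous filtering keeps exactly the zero-free features and is idempotent", {
  ft <- build_time_agnostic(tiny_long())
  ub <- filter_ubiquitous(ft)
  m <- ft_matrix(ub)
  # C16H26N2O8 is absent from S1, the other two formulas are detected everywhere
  expect_setequal(colnames(m), c("C6H12O6", "C10H16O8"))
  expect_true(all(m > 0))
  expect_equal(ft_matrix(filter_ubiquitous(ub)), m)
  expect_true("ubiquitous" %in% ft_provenance(ub)$filters)
})

test_that("low-variance filtering drops features above, and keeps features at, the zero-fraction cutoff", {
  # 20 samples; formula Rare appears in 1 sample (95% zeros, dropped),
  # Edge in 2 samples (90% zeros, exactly at the cutoff, kept),
  # Common in all samples.
  ids <- sprintf("S%02d", 1:20)
  long <- dplyr::bind_rows(
    tibble::tibble(sample_id = ids, segment_start = 12.3,
                   formula = "C6H12O6", intensity = 1),
    tibble::tibble(sample_id = ids[1:2], segment_start = 12.3,
                   formula = "C10H16O8", intensity = 2),
    tibble::tibble(sample_id = ids[1], segment_start = 12.3,
                   formula = "C16H26N2O8", intensity = 3)
  )
  ft <- filter_low_variance(build_time_agnostic(long))
  expect_setequal(colnames(ft_matrix(ft)), c("C6H12O6", "C10H16O8"))
  expect_equal(ft_matrix(filter_low_variance(ft)), ft_matrix(ft))
  # the combined elimination is the composition of the two filters
  both <- apply_preprocess(long,
    list(table_format = "time_agnostic", elimination = "both",
         normalization = "SUM"))
  expect_equal(ft_provenance(both)$filters, c("no_low_variance", "ubiquitous"))
  expect_setequal(colnames(ft_matrix(both)), "C6H12O6")
})

test_that("DOC normalization divides each sample row by its DOC concentration", {
  ft <- build_time_agnostic(tiny_long())
  out <- normalize_doc(ft, tiny_samples())
  expect_equal(ft_matrix(out), ft_matrix(ft) / c(50, 100))
  expect_equal(ft_provenance(out)$normalization, "DOC-N")
  expect_error(normalize_doc(ft, c(S1 = 50)), "Missing DOC")
  expect_error(normalize_doc(ft, c(S1 = 50, S2 = 0)), "Non-positive")
})

test_that("sum normalization makes each spectrum a unit composition", {
  # time-agnostic: one spectrum per sample row
  agn <- normalize_sum(build_time_agnostic(tiny_long()))
  expect_equal(unname(rowSums(ft_matrix(agn))), c(1, 1))
  # time-aware: one spectrum per (sample, segment) block
  aware <- normalize_sum(build_time_aware(tiny_long()))
  m <- ft_matrix(aware)
  segs <- ft_provenance(aware)$segments[colnames(m)]
  for (s in unique(segs)) {
    block <- m[, segs == s, drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, nrow(block)))
  }
  # hand-computed block: S1 at 12.3 min holds intensities 2 and 5
  expect_equal(m["S1", "C6H12O6@12.3"], 2 / 7)
  expect_equal(m["S1", "C10H16O8@12.3"], 5 / 7)
  # a single-feature spectrum normalizes to exactly 1
  expect_equal(m["S2", "C6H12O6@12.3"], 1)
})

test_that("ubiquitous-sum normalization uses only zero-free features in the denominator", {
  ft <- build_time_agnostic(tiny_long())
  out <- ft_matrix(normalize_ubisum(ft))
  # ubiquitous features are C6H12O6 and C10H16O8; denominators 3+5 and 6+3
  expect_equal(out["S1", "C6H12O6"], 3 / 8)
  expect_equal(out["S2", "C16H26N2O8"], 1 / 9)
  # denominator excludes the non-ubiquitous formula, so ubiquitous entries
  # per row sum to one while full rows can exceed one
  expect_equal(unname(rowSums(out[, c("C6H12O6", "C10H16O8")])), c(1, 1))
})

test_that("sum and ubiquitous-sum normalization coincide on ubiquitous-filtered tables", {
  sim <- small_sim()
  for (fmt in c("time_aware", "time_agnostic")) {
    ft <- apply_preprocess(sim$long,
      list(table_format = fmt, elimination = "ubiquitous",
           normalization = "SUM"))
    ub <- apply_preprocess(sim$long,
      list(table_format = fmt, elimination = "ubiquitous",
           normalization = "UBISUM"))
    expect_equal(ft_matrix(ft), ft_matrix(ub))
  }
})

test_that("ALR uses the minimum-variance ubiquitous reference and replaces zeros by a third of the detection floor", {
  ft <- build_time_agnostic(tiny_long())
  m <- ft_matrix(ft)
  out <- alr_transform(ft)
  ref <- attr(out, "alr_reference")
  # variance across samples: C6H12O6 var(3,6); C10H16O8 var(5,3) -> smaller
  expect_equal(ref, "C10H16O8")
  a <- ft_matrix(out)
  # the reference column is ln(1) = 0 everywhere
  expect_equal(unname(a[, ref]), c(0, 0))
  # zero entries were replaced by min-nonzero / 3 before the log-ratio
  expect_equal(a["S1", "C16H26N2O8"], log((1 / 3) / 5))
  expect_equal(a["S1", "C6H12O6"], log(3 / 5))
})

test_that("ALR is invariant to rescaling the whole table", {
  sim <- small_sim()
  ft <- build_time_agnostic(sim$long)
  scaled_long <- dplyr::mutate(sim$long, intensity = intensity * 7.3)
  a1 <- ft_matrix(alr_transform(ft))
  a2 <- ft_matrix(alr_transform(build_time_agnostic(scaled_long)))
  expect_equal(a1, a2)
})

test_that("an ALR reference tie is reported and resolved deterministically", {
  ids <- c("S1", "S2", "S3")
  long <- dplyr::bind_rows(
    tibble::tibble(sample_id = ids, segment_start = 12.3,
                   formula = "C6H12O6", intensity = c(1, 2, 3)),
    tibble::tibble(sample_id = ids, segment_start = 12.3,
                   formula = "C10H16O8", intensity = c(1, 2, 3))
  )
  expect_message(out <- alr_transform(build_time_agnostic(long)), "tie")
  expect_equal(attr(out, "alr_reference"), "C10H16O8")
})

test_that("target standardization centers, scales by the sample deviation, and inverts exactly", {
  withr::with_seed(8, x <- runif(30, 0.01, 0.06))
  sc <- zscore_target(x)
  expect_equal(mean(sc$values), 0)
  expect_equal(sd(sc$values), 1)
  # two points a unit apart: sample sd sqrt(2)/... here sd(c(1,3)) = sqrt(2)
  two <- zscore_target(c(1, 3))
  expect_equal(two$values, c(-1, 1) / sqrt(2))
  expect_equal(inverse_zscore(sc, sc$values), x)
  expect_equal(sc$range, range(x))
  expect_error(zscore_target(rep(2, 5)), "constant")
  expect_error(zscore_target(1), "at least two")
})

test_that("every preprocessing combination runs end to end with recorded provenance", {
  sim <- small_sim()
  specs <- preprocess_specs()
  for (i in seq_len(nrow(specs))) {
    ft <- apply_preprocess(sim$long, specs[i, ], samples = sim$samples)
    prov <- ft_provenance(ft)
    expect_equal(prov$time_aware, specs$table_format[i] == "time_aware")
    expect_equal(prov$normalization, specs$normalization[i])
    m <- ft_matrix(ft)
    expect_true(all(is.finite(m)))
    expect_equal(rownames(m), sort(unique(sim$long$sample_id)))
  }
})
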