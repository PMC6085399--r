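test_that("the generator is deterministic under seed and config", {
  cfg <- generator_config(seed = 13, n_formulae = 80, sample_ids = c("A", "B"))
  a <- generate_fullrange(cfg)
  b <- generate_fullrange(cfg)
  expect_identical(a$peaks, b$peaks)
  w <- isolation_window(a$truth$formulas$ion_mz[
    which.min(abs(a$truth$formulas$ion_mz - 370))])
  fa <- generate_fragmentation(a, w)
  fb <- generate_fragmentation(b, w)
  expect_identical(fa$peaks, fb$peaks)
  # a different replicate run changes only measurement noise
  fa2 <- generate_fragmentation(a, w, run = 2)
  expect_false(identical(fa$peaks$intensity, fa2$peaks$intensity))
})

test_that("generator output respects its configured invariants", {
  cfg <- generator_config(seed = 17, n_formulae = 120,
                          sample_ids = c("A", "B"))
  fr <- generate_fullrange(cfg)
  expect_true(all(fr$peaks$intensity >= 0))
  expect_true(all(fr$peaks$mz >= cfg$mass_min & fr$peaks$mz <= cfg$mass_max))
  # every non-noise peak traces to exactly one truth record
  pm <- fr$truth$peak_map
  expect_true(all(!is.na(pm$true_formula[pm$kind != "noise"])))
  expect_equal(nrow(fr$peaks), nrow(pm))
  # empty scenario
  empty <- generate_fullrange(generator_config(seed = 1, n_formulae = 0))
  expect_equal(nrow(empty$peaks), 0)
  expect_error(
    generator_config(seed = 1, class_mixture = c(black_carbon = 0.4)),
    "sum to 1"
  )
})

test_that("isotopologue companions sit one 13C mass difference above parents", {
  cfg <- generator_config(seed = 29, n_formulae = 60, sample_ids = "A",
                          ppm_jitter_sd = 0, noise_peak_rate = 0)
  fr <- generate_fullrange(cfg)
  pm <- fr$truth$peak_map
  mono <- pm[pm$kind == "formula", ]
  iso <- pm[pm$kind == "isotopologue", ]
  expect_equal(nrow(iso), nrow(mono))
  parent_counts <- as_formula(iso$true_formula)
  parent_counts$c13 <- 0L
  parent_str <- format_formula(parent_counts)
  j <- match(parent_str, mono$true_formula)
  expect_false(any(is.na(j)))
  expect_equal(iso$mz, mono$mz[j] + dom_masses()$d13C, tolerance = 1e-9)
  # companion intensity follows the binomial abundance expectation
  ratio <- iso$intensity / mono$intensity[j]
  expected <- as_formula(parent_str)$c * 0.0107 / (1 - 0.0107)
  expect_equal(ratio, expected, tolerance = 1e-9)
})

test_that("zero profile divergence gives identical mean profiles across samples", {
  cfg <- generator_config(seed = 43, n_formulae = 60,
                          sample_ids = c("A", "B"), profile_divergence = 0)
  fr <- generate_fullrange(cfg)
  expect_equal(fr$truth$profiles[["A"]], fr$truth$profiles[["B"]])
  cfg1 <- generator_config(seed = 43, n_formulae = 60,
                           sample_ids = c("A", "B"), profile_divergence = 1)
  fr1 <- generate_fullrange(cfg1)
  expect_false(isTRUE(all.equal(fr1$truth$profiles[["A"]],
                                fr1$truth$profiles[["B"]])))
})

test_that("the model-compound fixture separates isomers sharply", {
  fx <- make_model_compound_fixture()
  expect_equal(sort(unique(fx$sample_id)),
               paste0("btca_isomer_", 1:3))
  # all three share the benzenetricarboxylic acid precursor m/z
  prec_mz <- round(ion_mass("C9H6O6"), 5)
  for (s in unique(fx$sample_id)) {
    expect_true(any(round(fx$mz[fx$sample_id == s], 5) == prec_mz))
  }
  rel <- relative_intensities(attribute_fragments(fx, "C9H6O6"))
  fits <- all_pairs_regression(rel)
  expect_true(all(fits$delta_sl > 0.2))
  # an isomer against itself is exactly conforming
  dup <- dplyr::bind_rows(
    rel, dplyr::mutate(rel, sample_id = paste0(sample_id, "_bis"))
  )
  self <- paired_regression(dup, "btca_isomer_1", "btca_isomer_1_bis")
  expect_equal(self$delta_sl, 0, tolerance = 1e-12)
})

test_that("replicate runs land inside the analytical noise band", {
  cfg <- generator_config(seed = 47, n_formulae = 250,
                          sample_ids = c("A", "B"))
  fr <- generate_fullrange(cfg)
  asg <- truth_assigned(fr)
  wins <- select_windows(asg, k_windows = 8)
  r1 <- windows_rel(fr, asg, wins, run = 1)
  r2 <- windows_rel(fr, asg, wins, run = 2)
  both <- dplyr::bind_rows(
    dplyr::mutate(r1[r1$sample_id == "A", ], sample_id = "rep1"),
    dplyr::mutate(r2[r2$sample_id == "A", ], sample_id = "rep2")
  )
  bc <- replicate_variability(both, "rep1", "rep2")
  expect_gt(bc, 0.02)
  expect_lt(bc, 0.08)
})
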