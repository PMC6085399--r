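test_that("fragment-based carboxyl counts follow the multiplicity weighting", {
  rel <- tibble::tibble(
    precursor_formula = "F1",
    loss_label = c("2CO2", "2CO2+H2O"),
    rel_intensity = c(0.6, 0.4)
  )
  expect_equal(carboxyl_from_fragments(rel)$c_frag, 2)
  only_prec <- tibble::tibble(precursor_formula = "F1",
                              loss_label = "precursor", rel_intensity = 1)
  expect_equal(carboxyl_from_fragments(only_prec)$c_frag, 0)
  mix <- tibble::tibble(
    precursor_formula = "F1",
    loss_label = c("precursor", "CO2", "2CO2"),
    rel_intensity = c(0.5, 0.25, 0.25)
  )
  expect_equal(carboxyl_from_fragments(mix)$c_frag, 0.75)
  # invariant to uniform intensity scaling
  mix10 <- mix
  mix10$rel_intensity <- mix10$rel_intensity * 10
  expect_equal(carboxyl_from_fragments(mix10)$c_frag, 0.75)
  zero <- mix
  zero$rel_intensity <- 0
  expect_error(carboxyl_from_fragments(zero), "zero")
})

test_that("composition-based carboxyl estimates follow the linear model with the O/2 cap", {
  expect_equal(as.numeric(carboxyl_from_formula("C10H22", a = 0.5)), 0)
  expect_equal(as.numeric(carboxyl_from_formula("C18H22O8", a = 0.5)), 4)
  # two oxygens per carboxyl bound the estimate
  expect_equal(as.numeric(carboxyl_from_formula("C10H16O3", a = 2)), 1)
  # parameter recovery from known counts
  set.seed(6)
  f <- tibble::tibble(c = sample(10:25, 40, TRUE), o = sample(4:12, 40, TRUE))
  f$h <- 2L * f$c - 2L * sample(2:9, 40, TRUE)
  counts <- 0.2 * f$o + 0.05 * dbe(f) + 0.1
  fit <- fit_carboxyl_model(format_formula(f), counts)
  expect_equal(unname(fit["a"]), 0.2, tolerance = 1e-9)
  expect_equal(unname(fit["b"]), 0.05, tolerance = 1e-9)
  expect_lt(attr(fit, "rmse"), 1e-9)
})

test_that("the diversity index is the correlation of the two estimates", {
  est <- tibble::tibble(c_frag = seq(0.5, 2.4, length.out = 12))
  est$c_formula <- est$c_frag
  expect_equal(diversity_index(est), 1)
  anti <- est
  anti$c_formula <- rev(est$c_frag)
  expect_lt(diversity_index(anti), 0)
  expect_error(diversity_index(est[1:5, ]), "at least 10")
  flat <- est
  flat$c_formula <- 1
  expect_error(diversity_index(flat), "zero variance")
})

test_that("minimum isomer and compound numbers follow the dispersion ratio", {
  est <- tibble::tibble(c_frag = c(1, 2, 3, 1.5, 2.5, 1.2, 2.2, 0.8, 1.8, 2.8))
  est$c_formula <- est$c_frag + rnorm(10, 0, 0.2)
  s <- sd(est$c_frag - est$c_formula)
  expect_equal(min_isomers(est, sigma_single = s), 1)
  expect_equal(min_isomers(est, sigma_single = 10 * s), 100)
  ident <- est
  ident$c_formula <- ident$c_frag
  expect_warning(n0 <- min_isomers(ident, 0.5, cap = 999), "cap")
  expect_equal(n0, 999)
  expect_equal(min_compounds(10, 2531), 25310)
  expect_equal(min_compounds(1, 7), 7)
  expect_error(min_compounds(3, 0), "common")
})

test_that("carboxyl-estimate agreement strengthens with isomer multiplicity", {
  r_at <- function(iso) {
    cfg <- generator_config(seed = 41, n_formulae = 250, sample_ids = "A",
                            isomers_per_formula = iso)
    fr <- generate_fullrange(cfg)
    asg <- truth_assigned(fr)
    wins <- select_windows(asg, k_windows = 12)
    rel <- windows_rel(fr, asg, wins)
    est <- carboxyl_estimates(rel, model = cfg$carboxyl_model)
    diversity_index(est)
  }
  rs <- sapply(c(1, 10, 100), r_at)
  expect_true(all(diff(rs) > 0))
})
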