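make_rel <- function(values_by_sample) {
  purrr::map_dfr(names(values_by_sample), function(s) {
    v <- values_by_sample[[s]]
    tibble::tibble(
      sample_id = s,
      precursor_formula = paste0("F", seq_along(v)),
      loss_label = "CO2",
      rel_intensity = v
    )
  })
}

test_that("paired regression reproduces forced slopes exactly", {
  x <- c(0.1, 0.2, 0.3, 0.05, 0.15, 0.25)
  rel <- make_rel(list(a = x, b = x))
  fit <- paired_regression(rel, "a", "b")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$delta_sl, 0, tolerance = 1e-12)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  fit08 <- paired_regression(make_rel(list(a = x, b = 0.8 * x)), "a", "b")
  expect_equal(fit08$slope, 0.8, tolerance = 1e-12)
  expect_equal(fit08$delta_sl, 0.2, tolerance = 1e-12)
  expect_error(paired_regression(make_rel(list(a = rep(0.1, 5),
                                               b = x[1:5])), "a", "b"),
               "degenerate")
})

test_that("the outlier rule removes at most one gross point and reports it", {
  set.seed(8)
  x <- runif(30, 0, 0.3)
  y <- x
  y[7] <- x[7] + 0.5   # one gross outlier
  fit <- paired_regression(make_rel(list(a = x, b = y)), "a", "b")
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$excluded_keys, "F7:CO2")
  expect_lt(fit$delta_sl, fit$delta_sl_raw)
  expect_equal(fit$n, 29)
  g <- glance(fit)
  expect_true(all(c("slope", "delta_sl", "slope_raw", "n_excluded") %in%
                    names(g)))
  # clean data: nothing excluded
  clean <- paired_regression(make_rel(list(a = x, b = x * 1.02)), "a", "b")
  expect_equal(clean$n_excluded, 0)
})

test_that("Bray-Curtis matches its definition and the element-wise oracle", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(2, 0), c(1, 1)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 1), c(1, 1)), "non-negative")
  set.seed(5)
  for (i in 1:50) {
    x <- runif(20) * rbinom(20, 1, 0.8)
    y <- runif(20) * rbinom(20, 1, 0.8)
    expect_equal(bray_curtis(x, y), oracle_bray_curtis(x, y),
                 tolerance = 1e-12)
    expect_equal(bray_curtis(x, y), bray_curtis(y, x))
    expect_gte(bray_curtis(x, y), 0)
    expect_lte(bray_curtis(x, y), 1)
    # the vegan route used for matrices agrees with the scalar definition
    expect_equal(
      as.numeric(vegan::vegdist(rbind(x, y), method = "bray")),
      bray_curtis(x, y), tolerance = 1e-12
    )
  }
})

test_that("dissimilarity levels behave on identical and disjoint samples", {
  asg <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 3),
    mz = rep(c(200, 300, 400), 2),
    intensity = rep(c(5, 3, 2), 2),
    snr = 50, formula = rep(c("X", "Y", "Z"), 2),
    is_isotopologue = FALSE
  )
  rel <- make_rel(list(a = c(0.2, 0.3), b = c(0.2, 0.3)))
  rel$precursor_formula <- rep(c("X", "Y"), 2)
  dl <- dissimilarity_levels(asg, rel = rel)
  for (lv in names(dl$levels)) {
    expect_equal(max(dl$levels[[lv]]), 0, tolerance = 1e-12)
  }
  # disjoint formula sets: level 1 is 1, level 2 undefined
  dis <- asg
  dis$formula[dis$sample_id == "b"] <- c("U", "V", "W")
  expect_error(dissimilarity_levels(dis, rel = NULL), "common")
  long <- tidy(dl)
  expect_equal(nrow(long), 3)
  expect_true(all(c("sample_a", "sample_b", "level", "dissimilarity") %in%
                    names(long)))
})

test_that("replicate variability is zero for identical runs and grows under censoring", {
  v <- c(0.30, 0.25, 0.20, 0.15, 0.10)
  rel <- make_rel(list(r1 = v, r2 = v))
  expect_equal(replicate_variability(rel, "r1", "r2"), 0, tolerance = 1e-12)
  # censoring fragments one by one increases the dissimilarity monotonically
  bc <- sapply(1:3, function(k) {
    v2 <- v
    v2[seq_len(k)] <- 0
    replicate_variability(make_rel(list(r1 = v, r2 = v2)), "r1", "r2")
  })
  expect_true(all(diff(bc) > 0))
})

test_that("generator pairs with shared profiles sit near the identity line", {
  cfg <- generator_config(seed = 37, n_formulae = 250,
                          sample_ids = c("A", "B"))
  fr <- generate_fullrange(cfg)
  asg <- truth_assigned(fr)
  wins <- select_windows(asg, k_windows = 8)
  rel <- windows_rel(fr, asg, wins)
  common <- common_formulae(asg)$formulas
  fit <- paired_regression(rel[rel$precursor_formula %in% common, ], "A", "B")
  expect_gte(fit$n, 50)
  expect_lt(fit$delta_sl, 0.05)
  expect_gt(fit$r, 0.95)
})

test_that("profile divergence raises slope deviation and fragment dissimilarity", {
  stats_at <- function(delta) {
    cfg <- generator_config(seed = 37, n_formulae = 200,
                            sample_ids = c("A", "B"),
                            profile_divergence = delta)
    fr <- generate_fullrange(cfg)
    asg <- truth_assigned(fr)
    wins <- select_windows(asg, k_windows = 6)
    rel <- windows_rel(fr, asg, wins)
    common <- common_formulae(asg)$formulas
    relc <- rel[rel$precursor_formula %in% common, ]
    fit <- paired_regression(relc, "A", "B")
    dl <- dissimilarity_levels(asg, rel = relc, common = common)
    c(delta_sl = fit$delta_sl, bc3 = max(dl$levels$fragments))
  }
  res <- sapply(c(0, 0.5, 1), stats_at)
  expect_true(all(diff(res["delta_sl", ]) > 0))
  expect_true(all(diff(res["bc3", ]) > 0))
})
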