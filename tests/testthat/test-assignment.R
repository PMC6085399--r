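test_that("enumeration finds the expected candidates at known masses", {
  cons <- assignment_constraints()
  cand <- enumerate_candidates(365.12419, cons)
  expect_true("C18H22O8" %in% cand$formula)
  expect_lt(abs(cand$error_ppm[cand$formula == "C18H22O8"]), 0.01)
  cand2 <- enumerate_candidates(209.00916, cons)
  expect_true("C9H6O6" %in% cand2$formula)
  expect_equal(nrow(enumerate_candidates(150.0, cons, tol_ppm = 0.001)), 0)
  expect_error(enumerate_candidates(120, cons), "outside")
})

test_that("enumeration agrees with the brute-force oracle on random masses", {
  cons <- assignment_constraints(tol_ppm = 1)
  set.seed(2)
  for (mz in runif(25, 150, 700)) {
    expect_equal(candidate_keys(enumerate_candidates(mz, cons)),
                 oracle_enumerate(mz, 1))
  }
})

test_that("enumerated candidates respect every constraint", {
  cons <- assignment_constraints()
  set.seed(3)
  cand <- dplyr::bind_rows(lapply(runif(10, 200, 900), function(mz) {
    enumerate_candidates(mz, cons, tol_ppm = 5)
  }))
  expect_true(all(cand$o <= cand$c))
  expect_true(all(cand$h >= 0.3 * cand$c))
  d <- dbe(cand[, c("c", "h", "n", "o", "s", "p")])
  expect_true(all(d >= 0 & abs(d - round(d)) < 1e-9))
})

test_that("assignment recovers generator truth and is order-stable", {
  cfg <- generator_config(seed = 23, n_formulae = 150, sample_ids = "A")
  fr <- generate_fullrange(cfg)
  filt <- snr_filter(fr$peaks)
  asg <- assign_formulas(filt)
  pm <- fr$truth$peak_map[fr$truth$peak_map$kind == "formula" &
                            fr$truth$peak_map$snr >= 5, ]
  j <- dplyr::inner_join(asg, pm[c("sample_id", "mz", "true_formula")],
                         by = c("sample_id", "mz"))
  expect_equal(nrow(j), nrow(pm))
  recovery <- mean(!is.na(j$formula) & j$formula == j$true_formula)
  expect_gte(recovery, 0.99)
  # permutation of peak order does not change the result
  set.seed(1)
  perm <- filt[sample(nrow(filt)), ]
  asg_perm <- assign_formulas(peaklist(perm))
  expect_equal(dplyr::arrange(asg_perm, mz)$formula,
               dplyr::arrange(asg, mz)$formula)
})

test_that("isotopologue peaks are flagged with parent linkage and sanity checks", {
  base <- tibble::tibble(
    mz = c(ion_mass("C18H22O8"), ion_mass("C18H22O8") + dom_masses()$d13C),
    intensity = c(100, 100 * 18 * 0.0107 / 0.9893),
    snr = c(200, 40)
  )
  asg <- verify_isotopologues(assign_formulas(peaklist(base)))
  expect_true(asg$is_isotopologue[2])
  expect_equal(asg$formula[2], "[13C]1C17H22O8")
  expect_equal(asg$parent_formula[2], "C18H22O8")
  # same mass but no parent present: nothing to flag
  lone <- verify_isotopologues(assign_formulas(peaklist(base[2, ])))
  expect_false(lone$is_isotopologue[1])
  # implausible intensity (10x the binomial expectation) warns, not flags
  loud <- base
  loud$intensity[2] <- loud$intensity[2] * 10
  expect_warning(
    asg2 <- verify_isotopologues(assign_formulas(peaklist(loud))),
    "intensity ratio"
  )
  expect_false(asg2$is_isotopologue[2])
})

test_that("common formulas are the exact set intersection with shares", {
  asg <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2", "s3", "s3"),
    formula = c("A", "B", "C", "B", "C", "D", "B", "C"),
    is_isotopologue = FALSE
  )
  cm <- common_formulae(asg)
  expect_equal(cm$formulas, c("B", "C"))
  expect_equal(cm$shares$share_pct, c(2 / 3, 2 / 3, 1) * 100,
               tolerance = 1e-9)
  # disjoint sets intersect to nothing
  dis <- tibble::tibble(sample_id = c("a", "b"), formula = c("X", "Y"),
                        is_isotopologue = FALSE)
  expect_equal(length(common_formulae(dis)$formulas), 0)
  expect_error(common_formulae(dis[1, ]), "at least 2")
  # identical sets give 100% everywhere
  same <- tibble::tibble(sample_id = rep(c("a", "b"), each = 3),
                         formula = rep(c("X", "Y", "Z"), 2),
                         is_isotopologue = FALSE)
  expect_equal(common_formulae(same)$shares$share_pct, c(100, 100))
})
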