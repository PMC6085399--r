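test_that("the loss table prints the documented exact masses", {
  lt <- neutral_loss_table()
  major <- lt[lt$is_major, ]
  expect_equal(major$label,
               c("CO2", "2CO2", "3CO2", "H2O", "CO2+H2O", "2CO2+H2O",
                 "CH3OH", "CO2+CH3OH", "2CO2+CH3OH"))
  expect_equal(lt$exact_mass, neutral_mass(lt$formula), tolerance = 1e-6)
  expect_equal(round(lt$exact_mass[lt$label == "CO2"], 5), 43.98983)
  expect_equal(round(lt$exact_mass[lt$label == "2CO2+H2O"], 5), 105.99022)
})

test_that("fragment prediction subtracts losses with availability checks", {
  pred <- predict_fragments("C18H22O8")
  co2 <- pred[pred$loss_label == "CO2", ]
  expect_equal(round(co2$fragment_mz, 5), 321.13436)
  expect_equal(co2$fragment_formula, "C17H22O6")
  pred9 <- predict_fragments("C9H6O6")
  f3 <- pred9[pred9$loss_label == "3CO2", ]
  expect_equal(f3$fragment_formula, "C6H6")
  expect_equal(round(f3$fragment_mz, 5), 77.03967)
  # a CH4-like precursor cannot lose CO2
  ch4 <- predict_fragments("CH4")
  expect_false(ch4$applicable[ch4$loss_label == "CO2"])
  # round trip: fragment + loss = precursor
  ok <- pred[pred$applicable, ]
  for (i in seq_len(nrow(ok))) {
    lf <- neutral_loss_table()
    back <- formula_add(ok$fragment_formula[i],
                        lf$formula[lf$label == ok$loss_label[i]])
    expect_equal(format_formula(back), "C18H22O8")
  }
})

test_that("fragment spectra calibrate against predicted ion masses", {
  prec <- "C18H22O8"
  pred <- predict_fragments(prec)
  mz_true <- c(ion_mass(prec), pred$fragment_mz[pred$applicable])
  pl <- peaklist(tibble::tibble(mz = sort(mz_true) * (1 + 0.4e-6),
                                intensity = 10, snr = 50))
  res <- calibrate_fragment_spectrum(pl, prec)
  expect_lt(res$calibration$max_abs_ppm, 0.02)
  expect_equal(res$calibration$offset_ppm, 0.4, tolerance = 0.02)
  # no matches at all -> calibration failure
  off <- peaklist(tibble::tibble(mz = c(150.5, 160.5, 170.5),
                                 intensity = 1, snr = 10))
  expect_error(calibrate_fragment_spectrum(off, prec), "calibration failed")
})

test_that("attribution resolves close precursors and flags degeneracies", {
  # two precursors separated by the CH4/O spacing (36.4 mDa)
  p1 <- "C18H22O8"
  p2 <- "C19H26O7"
  expect_equal(abs(ion_mass(p1) - ion_mass(p2)), 0.0364, tolerance = 1e-3)
  frag_mz <- ion_mass(p1) - neutral_mass("CO2")
  pl <- peaklist(tibble::tibble(mz = frag_mz, intensity = 5, snr = 25))
  rec <- attribute_fragments(pl, c(p1, p2))
  expect_equal(rec$precursor_formula, p1)
  expect_equal(rec$loss_label, "CO2")
  expect_false(rec$ambiguous)
  # a constructed degenerate explanation is flagged ambiguous and excluded
  losses2 <- tibble::tibble(
    label = c("L1", "L2"), formula = c("CO2", "CO2"),
    is_major = TRUE, n_co2 = 1L, exact_mass = neutral_mass(c("CO2", "CO2"))
  )
  rec2 <- attribute_fragments(pl, p1, losses = losses2)
  expect_true(rec2$ambiguous[1])
  # empty fragment spectrum gives an empty record table
  empty <- peaklist(tibble::tibble(mz = numeric(), intensity = numeric(),
                                   snr = numeric()))
  expect_equal(nrow(attribute_fragments(empty, p1)), 0)
})

test_that("ambiguous intensity can be split in proportion to precursors", {
  p1 <- "C18H22O8"
  losses2 <- tibble::tibble(
    label = c("L1", "L2"), formula = c("CO2", "CO2"),
    is_major = TRUE, n_co2 = 1L, exact_mass = neutral_mass(c("CO2", "CO2"))
  )
  pl <- peaklist(tibble::tibble(
    mz = c(ion_mass(p1), ion_mass(p1) - neutral_mass("CO2")),
    intensity = c(50, 8), snr = c(100, 16)
  ))
  rec <- attribute_fragments(pl, p1, losses = losses2, ambiguous = "split")
  split_rows <- rec[rec$loss_label %in% c("L1", "L2"), ]
  expect_equal(nrow(split_rows), 2)
  expect_equal(sum(split_rows$intensity), 8)
})

test_that("relative intensities partition I_Tot exactly", {
  rec <- tibble::tibble(
    mz = c(365.124, 321.134, 347.114),
    intensity = c(80, 15, 5), snr = c(100, 20, 8),
    precursor_formula = "C18H22O8",
    loss_label = c("precursor", "CO2", "H2O"),
    is_major = TRUE, predicted_mz = NA_real_, error_ppm = 0,
    ambiguous = FALSE
  )
  rel <- relative_intensities(rec)
  expect_equal(rel$rel_intensity[rel$loss_label == "precursor"], 0.80)
  expect_equal(rel$rel_intensity[rel$loss_label == "CO2"], 0.15)
  expect_equal(rel$rel_intensity[rel$loss_label == "H2O"], 0.05)
  expect_equal(sum(rel$rel_intensity), 1, tolerance = 1e-12)
  # absent fragments appear as explicit zeros
  expect_equal(nrow(rel), 10)
  # precursor only -> share 1
  rel1 <- relative_intensities(rec[1, ])
  expect_equal(rel1$rel_intensity[rel1$loss_label == "precursor"], 1)
  # fragments without their precursor cannot be normalized
  expect_error(suppressWarnings(relative_intensities(rec[-1, ])),
               "precursor")
})

test_that("the common detection limit is the cross-sample minimum and censors symmetrically", {
  snr_tbl <- tibble::tibble(
    sample_id = c("a", "b", "c"), precursor_formula = "F1",
    snr = c(120, 85, 210)
  )
  lim <- common_detection_limit(snr_tbl)
  expect_equal(lim$common_limit, 85)
  expect_equal(common_detection_limit(snr_tbl[1, ])$common_limit, 120)
  # a fragment below threshold in ONE sample is zeroed in ALL samples
  rel <- tidyr::expand_grid(
    sample_id = c("a", "b"), precursor_formula = "F1",
    loss_label = c("precursor", "CO2", "H2O")
  )
  rel$rel_intensity <- c(0.9, 0.095, 0.005, 0.5, 0.3, 0.2)
  rel$intensity <- rel$rel_intensity * 100
  snr2 <- tibble::tibble(sample_id = c("a", "b"),
                         precursor_formula = "F1", snr = c(50, 300))
  cen <- censor_below_common_limit(rel, snr2)  # threshold = 1/50 = 0.02
  h2o <- cen[cen$loss_label == "H2O", ]
  expect_equal(h2o$rel_intensity, c(0, 0))       # 0.005 < 0.02 in sample a
  co2 <- cen[cen$loss_label == "CO2", ]
  expect_equal(co2$rel_intensity, c(0.095, 0.3)) # above threshold everywhere
  expect_equal(cen$rel_intensity[cen$loss_label == "precursor"], c(0.9, 0.5))
})

test_that("attribution recovers the generator's emitted (precursor, loss) pairs", {
  cfg <- generator_config(seed = 31, n_formulae = 250, sample_ids = c("A", "B"))
  fr <- generate_fullrange(cfg)
  asg <- truth_assigned(fr)
  wins <- select_windows(asg, k_windows = 6)
  hits <- 0; total <- 0
  for (w in wins) {
    fg <- generate_fragmentation(fr, w)
    rec <- attribute_fragments(fg$peaks, window_precursors(asg, w))
    got <- rec[!is.na(rec$precursor_formula) & !rec$ambiguous, ]
    truth_live <- fg$truth[fg$truth$true_rel > 0, ]
    key <- function(d) paste(d$sample_id, d$precursor_formula, d$loss_label)
    hits <- hits + sum(key(truth_live) %in% key(got))
    total <- total + nrow(truth_live)
  }
  expect_gte(hits / total, 0.99)
})
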