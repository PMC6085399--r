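#' Configuration of the synthetic FT-ICR-MS spectrum generator
#'
#' Defines a complete multi-sample study scenario with known ground truth:
#' full-range spectra (formulas arranged in CH2 homologous series under a
#' bell-shaped intensity envelope, thirteen-C1 isotopologues, ppm-scale mass
#' jitter and systematic calibration offset, random noise peaks) and
#' precursor-isolated fragmentation spectra whose neutral-loss profiles are
#' tied to per-isomer carboxyl counts.
#'
#' The single most important knob for the universality question is
#' `profile_divergence` (delta in \[0, 1\]): each sample's mean fragmentation
#' profile per formula is interpolated between a shared global profile
#' (`delta = 0`: all samples fragment identically, up to noise) and an
#' independent per-sample random profile (`delta = 1`). The isomer dimension
#' is controlled by `isomers_per_formula` together with
#' (`carboxyl_sigma_single`): each formula is backed by that many isomers
#' whose carboxyl counts scatter around a compositional expectation
#' `a * O + b * DBE + c0`, and the emitted profile is the average over the
#' isomer profiles, so carboxyl-estimate agreement strengthens with isomer
#' number exactly as the central-limit argument predicts.
#'
#' @param seed Integer seed; all generator randomness derives from it and
#'   identical (seed, config) pairs give bit-identical output.
#' @param sample_ids Sample labels (defaults to the five study environments).
#' @param n_formulae Number of distinct molecular formulas.
#' @param mass_min,mass_max Detected mass window (Da).
#' @param envelope_center,envelope_width Center and width (Da) of the
#'   Gaussian log-intensity envelope over m/z.
#' @param series_length Target length of each CH2 homologous series.
#' @param class_mixture Named proportions over [dom_classes()] (must sum to
#'   1; classes with proportion 0 are skipped).
#' @param common_fraction Fraction of formulas present in every sample;
#'   the rest occur in random sample subsets.
#' @param abundance_sd Log-scale SD of per-sample abundance factors (drives
#'   formula-level compositional dissimilarity without touching structure).
#' @param intensity_noise_sd Multiplicative (log-scale) measurement noise on
#'   every emitted intensity.
#' @param ppm_jitter_sd Random mass error SD (ppm).
#' @param calibration_offset_ppm Systematic mass offset (ppm); scalar or one
#'   value per sample.
#' @param noise_peak_rate Noise peaks per true formula peak.
#' @param isotopologues Emit thirteen-C1 companion peaks.
#' @param noise_floor Detector noise level; `snr = intensity / noise_floor`.
#' @param isomers_per_formula Isomers behind each formula.
#' @param carboxyl_model Named vector `c(a, b, c0)` of the compositional
#'   carboxyl expectation.
#' @param carboxyl_sigma_single Per-isomer carboxyl SD around that
#'   expectation.
#' @param precursor_share Fraction of each isomer's ion population surviving
#'   as the precursor ion (collision conditions always leave a survivor
#'   ion); the remainder fragments.
#' @param profile_divergence delta in \[0, 1\], see above.
#' @param dirichlet_concentration Concentration of the per-isomer Dirichlet
#'   emission sampler (larger = less profile sampling noise).
#' @param frag_noise_floor Noise level of fragmentation scans.
#' @return A `dom_generator_config` list.
#' @export
generator_config <- function(seed = 1,
                             sample_ids = c("AABW", "NADW", "EMW",
                                            "NorthSea", "Lake"),
                             n_formulae = 500,
                             mass_min = 150, mass_max = 2000,
                             envelope_center = 370, envelope_width = 110,
                             series_length = 8,
                             class_mixture = c(
                               black_carbon = 0.05,
                               polyphenol_o_rich = 0.10,
                               polyphenol_o_poor = 0.08,
                               highly_unsaturated = 0.60,
                               aliphatic = 0.12,
                               other = 0.05
                             ),
                             common_fraction = 0.6,
                             abundance_sd = 0.3,
                             intensity_noise_sd = 0.05,
                             ppm_jitter_sd = 0.2,
                             calibration_offset_ppm = 0,
                             noise_peak_rate = 0.1,
                             isotopologues = TRUE,
                             noise_floor = 0.5,
                             isomers_per_formula = 10,
                             carboxyl_model = c(a = 0.10, b = 0.02, c0 = 0),
                             carboxyl_sigma_single = 0.5,
                             precursor_share = 0.25,
                             profile_divergence = 0,
                             dirichlet_concentration = 500,
                             frag_noise_floor = 0.2) {
  stopifnot(length(seed) == 1, seed == floor(seed),
            n_formulae >= 0, mass_min < mass_max,
            profile_divergence >= 0, profile_divergence <= 1,
            isomers_per_formula >= 1, common_fraction >= 0,
            common_fraction <= 1)
  if (abs(sum(class_mixture) - 1) > 1e-8) {
    abort("class_mixture proportions must sum to 1")
  }
  structure(
    as.list(environment()),
    class = "dom_generator_config"
  )
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
.subseed <- function(seed, ...) {
  ix <- c(...)
  s <- (as.double(seed) %% 2147483647)
  mult <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(ix)) {
    s <- (s * 31 + mult[(i - 1) %% 4 + 1] * (as.double(ix[i]) + 1)) %%
      2147483647
  }
  as.integer(s)
}

# enumerate a pool of plausible CHO(N,S) compositions in a mass band and
# index it by compound class; used to seed CH2 homologous series
.formula_pool <- function(mass_min, mass_max) {
  grid <- expand.grid(c = 6:40, o = 0:30, d = 0:15, n = c(0L, 1L),
                      KEEP.OUT.ATTRS = FALSE)
  grid$h <- 2L + 2L * grid$c + grid$n - 2L * grid$d
  grid <- grid[grid$h >= 1 & grid$o <= grid$c &
                 grid$h >= 0.3 * grid$c & grid$h <= 2 * grid$c + 2, ]
  f <- tibble(c = grid$c, h = as.integer(grid$h), n = grid$n,
              o = grid$o, s = 0L, p = 0L, c13 = 0L, n15 = 0L)
  mz <- ion_mass(f)
  keep <- mz >= mass_min & mz <= mass_max
  f <- f[keep, ]
  f$ion_mz <- mz[keep]
  f$class <- as.character(classify_formula(f))
  f$formula <- format_formula(f)
  as_tibble(f)
}

# random mass error: zero-mean normal truncated at +/- 2 SD. Post-calibration
# FT-ICR mass errors are bounded — a peak drifting far outside the accuracy
# band would have been flagged at calibration — so unbounded Gaussian tails
# are not physical.
.rjitter <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  lo <- stats::pnorm(-2)
  stats::qnorm(runif(n, lo, 1 - lo)) * sd
}

.rdirichlet <- function(alpha) {
  x <- rgamma(length(alpha), shape = pmax(alpha, 1e-12))
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# signal layout of a fragmentation profile: precursor + the 9 major losses
.profile_signals <- function() {
  c("precursor", "CO2", "2CO2", "3CO2", "H2O", "CO2+H2O", "2CO2+H2O",
    "CH3OH", "CO2+CH3OH", "2CO2+CH3OH")
}

.signal_nco2 <- function() {
  c(precursor = 0L, "CO2" = 1L, "2CO2" = 2L, "3CO2" = 3L, "H2O" = 0L,
    "CO2+H2O" = 1L, "2CO2+H2O" = 2L, "CH3OH" = 0L, "CO2+CH3OH" = 1L,
    "2CO2+CH3OH" = 2L)
}

# profile of a single isomer with carboxyl count k, restricted to the losses
# the precursor can physically perform. A fixed share of the ion population
# survives as the precursor (collision conditions leave a visible survivor
# ion); the fragment mass is distributed over decarboxylation multiplicities
# as Binomial(max_mult, q) with q solved so that the intensity-weighted mean
# multiplicity over ALL signals (precursor included at multiplicity 0)
# equals k: q = k / ((1 - precursor_share) * max_mult), capped at 0.95.
# Within each multiplicity class the mass is split over its *applicable*
# members (pure mCO2 vs the +H2O / +CH3OH combinations), so dropping an
# unavailable combination never shifts the expected multiplicity.
.isomer_profile <- function(k, precursor_share, max_mult = 3,
                            applicable = .profile_signals()) {
  sig <- .profile_signals()
  members <- list(
    `0` = c("H2O", "CH3OH"),
    `1` = c("CO2", "CO2+H2O", "CO2+CH3OH"),
    `2` = c("2CO2", "2CO2+H2O", "2CO2+CH3OH"),
    `3` = "3CO2"
  )
  base_w <- list(
    `0` = c(0.75, 0.25),
    `1` = c(0.55, 0.30, 0.15),
    `2` = c(0.55, 0.30, 0.15),
    `3` = 1
  )
  frag_mass <- 1 - precursor_share
  if (max_mult > 0) {
    q <- min(max(k / (frag_mass * max_mult), 0), 0.95)
    w <- dbinom(0:max_mult, max_mult, q)
  } else {
    w <- 1
  }
  prof <- setNames(numeric(length(sig)), sig)
  prof["precursor"] <- precursor_share
  for (m in 0:max_mult) {
    mem <- members[[as.character(m)]]
    bw <- base_w[[as.character(m)]] * (mem %in% applicable)
    if (!any(bw > 0)) {
      # no applicable carrier in this class: the mass stays on the precursor
      prof["precursor"] <- prof["precursor"] + frag_mass * w[m + 1]
      next
    }
    prof[mem] <- prof[mem] + frag_mass * w[m + 1] * bw / sum(bw)
  }
  prof / sum(prof)
}

#' Generate synthetic full-range spectra with ground truth
#'
#' Builds the formula universe (CH2 series seeded per compound class from an
#' enumerated pool), per-sample presence and abundances, and emits one
#' centroided peak list per sample: true \eqn{[M-H]^-} masses perturbed by
#' the configured systematic ppm offset plus random jitter, intensities from
#' the bell envelope with per-formula and per-sample log-normal factors and
#' multiplicative measurement noise, thirteen-C1 isotopologue companions at
#' binomial abundance, and uniformly placed noise peaks drawn from the low
#' intensity tail. Every non-noise peak traces to exactly one truth record.
#'
#' @param config A [generator_config()].
#' @return List with `peaks` (multi-sample peak list) and `truth` (list:
#'   `formulas` — one row per formula with composition, class, true ion
#'   m/z, isomer carboxyl counts as a matrix in `isomer_k`; `abundance` —
#'   long table of per-(sample, formula) presence and true base intensity;
#'   `profiles` — per-(formula, sample) mean fragmentation profiles;
#'   `peak_map` — one row per emitted peak with its `kind`
#'   (formula/isotopologue/noise) and `true_formula`, so every non-noise
#'   peak traces to exactly one truth record; `offsets` — per-sample
#'   injected ppm offset; `noise` — emitted noise peaks; `config`).
#' @export
generate_fullrange <- function(config) {
  stopifnot(inherits(config, "dom_generator_config"))
  cfg <- config
  set.seed(.subseed(cfg$seed, 1))
  samples <- cfg$sample_ids
  ns <- length(samples)
  offsets <- rep(cfg$calibration_offset_ppm, length.out = ns)

  if (cfg$n_formulae == 0) {
    peaks <- peaklist(tibble(mz = numeric(), intensity = numeric(),
                             snr = numeric(),
                             sample_id = character()))
    return(list(peaks = peaks,
                truth = list(formulas = tibble(), abundance = tibble(),
                             profiles = list(), offsets = offsets,
                             noise = tibble(), config = cfg)))
  }

  # --- formula universe: CH2 series seeded per class -----------------------
  pool <- .formula_pool(cfg$mass_min,
                        min(cfg$mass_max, cfg$envelope_center * 2))
  mix <- cfg$class_mixture[cfg$class_mixture > 0]
  target <- round(mix * cfg$n_formulae)
  chosen <- list()
  for (cl in names(target)) {
    sub <- pool[pool$class == cl & pool$ion_mz <= cfg$envelope_center * 1.4, ]
    if (nrow(sub) == 0) {
      abort(sprintf("class mixture infeasible: no seed formulas of class '%s'",
                    cl))
    }
    need <- target[[cl]]
    n_series <- max(1, ceiling(need / cfg$series_length))
    seeds <- sub[sample.int(nrow(sub), min(n_series, nrow(sub))), ]
    ext <- purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
      k <- 0:(cfg$series_length - 1)
      tibble(c = seeds$c[i] + k, h = seeds$h[i] + 2L * k, n = seeds$n[i],
             o = seeds$o[i], s = 0L, p = 0L, c13 = 0L, n15 = 0L,
             series = paste0(cl, "_", i))
    })
    ext <- ext[ext$h <= 2 * ext$c + 2, ]
    chosen[[cl]] <- ext
  }
  fml <- bind_rows(chosen)
  fml$formula <- format_formula(fml)
  fml <- fml[!duplicated(fml$formula), ]
  fml$ion_mz <- ion_mass(fml)
  fml <- fml[fml$ion_mz >= cfg$mass_min & fml$ion_mz <= cfg$mass_max, ]
  # drop compositions closer than the resolving limit of the peak-list model
  fml <- fml[order(fml$ion_mz), ]
  fml <- fml[c(TRUE, diff(fml$ion_mz) > 5e-4), ]
  if (nrow(fml) > cfg$n_formulae) {
    fml <- fml[sort(sample.int(nrow(fml), cfg$n_formulae)), ]
  }
  fml$class <- as.character(classify_formula(fml))
  nf <- nrow(fml)

  # --- isomer carboxyl truth ----------------------------------------------
  # the carboxyl expectation is linear in composition but capped by the
  # largest decarboxylation multiplicity the formula can perform
  losses_tbl <- neutral_loss_table()
  applicable <- lapply(seq_len(nf), function(fi) {
    pr <- predict_fragments(fml[fi, ], losses_tbl)
    pr$loss_label[pr$applicable]
  })
  max_mult <- vapply(applicable, function(a) {
    max(c(0L, losses_tbl$n_co2[losses_tbl$label %in% a &
                                 !grepl("[+]", losses_tbl$label)]))
  }, integer(1))
  cm <- cfg$carboxyl_model
  k_lin <- cm[["a"]] * fml$o + cm[["b"]] * dbe(fml) + cm[["c0"]]
  # representable range of the intensity-weighted multiplicity mean: the
  # precursor survivor share carries weight 0 and the binomial success
  # probability is capped at 0.95 (see .isomer_profile)
  k_cap <- 0.95 * (1 - cfg$precursor_share) * max_mult
  k_mean <- pmin(pmax(k_lin, 0), 0.9 * k_cap)
  isomer_k <- matrix(
    pmin(pmax(rnorm(nf * cfg$isomers_per_formula, mean = rep(k_mean,
      cfg$isomers_per_formula), sd = cfg$carboxyl_sigma_single), 0),
      rep(k_cap, cfg$isomers_per_formula)),
    nrow = nf
  )
  fml$k_mean <- k_mean
  fml$max_mult <- max_mult

  # --- per-sample presence and abundance ----------------------------------
  is_common <- runif(nf) < cfg$common_fraction
  richness <- rlnorm(nf, meanlog = 0, sdlog = 0.5)
  abundance <- purrr::map_dfr(seq_along(samples), function(si) {
    present <- is_common | runif(nf) < 0.5
    present[sample.int(nf, 1)] <- TRUE   # never an empty sample
    envelope <- 100 * exp(-(fml$ion_mz - cfg$envelope_center)^2 /
                            (2 * cfg$envelope_width^2))
    base <- envelope * richness * rlnorm(nf, 0, cfg$abundance_sd)
    tibble(sample_id = samples[si], formula = fml$formula,
           present = present, base_intensity = base)
  })

  # --- per-(formula, sample) mean fragmentation profiles -------------------
  sig <- .profile_signals()
  shared <- lapply(seq_len(nf), function(fi) {
    rowMeans(vapply(seq_len(cfg$isomers_per_formula), function(j) {
      .isomer_profile(isomer_k[fi, j], cfg$precursor_share,
                      max_mult = max_mult[fi],
                      applicable = applicable[[fi]])
    }, numeric(length(sig))))
  })
  profiles <- list()
  for (si in seq_along(samples)) {
    set.seed(.subseed(cfg$seed, 2, si))
    profiles[[samples[si]]] <- lapply(seq_len(nf), function(fi) {
      own <- .rdirichlet(rep(2, length(sig)))
      names(own) <- sig
      (1 - cfg$profile_divergence) * shared[[fi]] +
        cfg$profile_divergence * own
    })
  }

  # --- emit peaks ----------------------------------------------------------
  m <- dom_masses()
  out <- vector("list", ns)
  noise_all <- vector("list", ns)
  for (si in seq_along(samples)) {
    set.seed(.subseed(cfg$seed, 3, si))
    ab <- abundance[abundance$sample_id == samples[si], ]
    sel <- which(ab$present)
    mz_true <- fml$ion_mz[sel]
    inten <- ab$base_intensity[sel] *
      rlnorm(length(sel), 0, cfg$intensity_noise_sd)
    ppm <- offsets[si] + .rjitter(length(sel), cfg$ppm_jitter_sd)
    df <- tibble(
      mz = mz_true * (1 + ppm * 1e-6),
      intensity = inten,
      snr = inten / cfg$noise_floor,
      sample_id = samples[si],
      kind = "formula",
      true_formula = fml$formula[sel]
    )
    if (cfg$isotopologues) {
      iso_true <- mz_true + m$d13C
      iso_int <- inten * fml$c[sel] * m$abundance_13C / (1 - m$abundance_13C)
      ppm_i <- offsets[si] + .rjitter(length(sel), cfg$ppm_jitter_sd)
      iso_formula <- fml[sel, ]
      iso_formula$c13 <- 1L
      df <- bind_rows(df, tibble(
        mz = iso_true * (1 + ppm_i * 1e-6),
        intensity = iso_int,
        snr = iso_int / cfg$noise_floor,
        sample_id = samples[si],
        kind = "isotopologue",
        true_formula = format_formula(iso_formula)
      ))
    }
    n_noise <- round(cfg$noise_peak_rate * length(sel))
    if (n_noise > 0) {
      lo <- max(cfg$mass_min, cfg$envelope_center - 2 * cfg$envelope_width)
      hi <- min(cfg$mass_max, cfg$envelope_center + 2 * cfg$envelope_width)
      nz <- tibble(
        mz = runif(n_noise, lo, hi),
        intensity = rlnorm(n_noise, log(6 * cfg$noise_floor), 0.4),
        sample_id = samples[si],
        kind = "noise",
        true_formula = NA_character_
      )
      nz$snr <- nz$intensity / cfg$noise_floor
      noise_all[[si]] <- nz
      df <- bind_rows(df, nz[names(df)])
    }
    df <- df[order(df$mz), ]
    df <- df[c(TRUE, diff(df$mz) > 1e-6), ]
    out[[si]] <- df
  }
  all_peaks <- bind_rows(out)
  peaks <- peaklist(all_peaks[c("mz", "intensity", "snr", "sample_id")])
  fml$isomer_k <- isomer_k
  list(
    peaks = peaks,
    truth = list(
      formulas = fml, abundance = abundance, profiles = profiles,
      peak_map = as_tibble(all_peaks),
      offsets = setNames(offsets, samples),
      noise = bind_rows(noise_all), config = cfg
    )
  )
}

#' Generate synthetic fragmentation spectra for an isolation window
#'
#' For every true formula whose ion falls inside the window and which is
#' present in a sample, draws the emitted neutral-loss profile (the average
#' of per-isomer Dirichlet draws around the sample's mean profile from the
#' full-range truth), removes physically impossible losses (insufficient
#' atoms), scales by the precursor's full-range intensity, applies
#' multiplicative intensity noise and ppm mass jitter plus the configured
#' offset, and returns the per-sample fragmentation peak lists together with
#' the emitted ground truth.
#'
#' The `run` index changes only the measurement-noise draws, so two runs
#' with the same `run`-independent truth are analytical replicates of the
#' same sample.
#'
#' @param fullrange Output of [generate_fullrange()].
#' @param window An [isolation_window()].
#' @param run Replicate index (default 1).
#' @param offset_ppm Systematic mass offset of the fragmentation scans
#'   (defaults to the full-range per-sample offsets).
#' @return List with `peaks` (multi-sample fragmentation peak list) and
#'   `truth` (tibble of emitted signals: sample, precursor formula, loss
#'   label, true m/z, true relative intensity).
#' @export
generate_fragmentation <- function(fullrange, window, run = 1,
                                   offset_ppm = NULL) {
  truth <- fullrange$truth
  cfg <- truth$config
  stopifnot(inherits(window, "dom_window"))
  fml <- truth$formulas
  in_win <- which(abs(fml$ion_mz - window$center) <= window$width / 2)
  if (length(in_win) == 0) abort("isolation window contains no precursor")
  samples <- cfg$sample_ids
  if (is.null(offset_ppm)) offset_ppm <- truth$offsets
  offset_ppm <- rep(offset_ppm, length.out = length(samples))
  sig <- .profile_signals()
  losses <- neutral_loss_table()
  loss_mass <- setNames(losses$exact_mass, losses$label)

  peak_rows <- list()
  truth_rows <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    ab <- truth$abundance[truth$abundance$sample_id == s, ]
    for (fi in in_win) {
      if (!ab$present[fi]) next
      set.seed(.subseed(cfg$seed, 4, si, fi, run))
      mean_prof <- truth$profiles[[s]][[fi]]
      emit <- rowMeans(vapply(seq_len(cfg$isomers_per_formula), function(j) {
        .rdirichlet(cfg$dirichlet_concentration * mean_prof)
      }, numeric(length(sig))))
      names(emit) <- sig
      # physical availability: a loss must leave a valid [M-H]- fragment
      pred <- predict_fragments(fml[fi, ], losses)
      ok_loss <- pred$loss_label[pred$applicable]
      keep <- names(emit) == "precursor" | names(emit) %in% ok_loss
      emit[!keep] <- 0
      emit <- emit / sum(emit)
      total <- ab$base_intensity[fi] *
        rlnorm(1, 0, cfg$intensity_noise_sd)
      mz_true <- ifelse(sig == "precursor", fml$ion_mz[fi],
                        fml$ion_mz[fi] - loss_mass[sig])
      inten <- total * emit *
        rlnorm(length(sig), 0, cfg$intensity_noise_sd)
      inten[emit == 0] <- 0
      ppm <- offset_ppm[si] + .rjitter(length(sig), cfg$ppm_jitter_sd)
      live <- inten > 0
      peak_rows[[length(peak_rows) + 1]] <- tibble(
        mz = mz_true[live] * (1 + ppm[live] * 1e-6),
        intensity = inten[live],
        snr = inten[live] / cfg$frag_noise_floor,
        sample_id = s
      )
      truth_rows[[length(truth_rows) + 1]] <- tibble(
        sample_id = s, precursor_formula = fml$formula[fi],
        loss_label = sig, true_mz = mz_true, true_rel = emit
      )
    }
  }
  if (length(peak_rows) == 0) {
    abort("no precursor of the window is present in any sample")
  }
  pk <- bind_rows(peak_rows)
  pk <- pk %>%
    arrange(.data$sample_id, .data$mz) %>%
    group_by(.data$sample_id) %>%
    filter(c(TRUE, diff(.data$mz) > 1e-6)) %>%
    ungroup()
  list(peaks = peaklist(pk), truth = bind_rows(truth_rows))
}

#' Model-compound fragmentation fixture
#'
#' Three synthetic fragmentation spectra standing in for the three isomers of
#' benzenetricarboxylic acid (C9H6O6, \eqn{[M-H]^-} at m/z 209.00916): same
#' precursor mass, deliberately different neutral-loss profiles. Structurally
#' distinct pure compounds must yield large regression slope deviations when
#' compared — the logic by which model compounds validate the fragmentation
#' statistics — whereas DOM samples sharing structures do not.
#'
#' @return A multi-sample peak list with `sample_id` in
#'   `btca_isomer_1..3`; deterministic (no randomness).
#' @export
make_model_compound_fixture <- function() {
  prof <- list(
    btca_isomer_1 = c(precursor = 0.15, "CO2" = 0.32, "2CO2" = 0.24,
                      "3CO2" = 0.14, "H2O" = 0.05, "CO2+H2O" = 0.06,
                      "2CO2+H2O" = 0.04, "CH3OH" = 0, "CO2+CH3OH" = 0,
                      "2CO2+CH3OH" = 0),
    btca_isomer_2 = c(precursor = 0.08, "CO2" = 0.10, "2CO2" = 0.42,
                      "3CO2" = 0.26, "H2O" = 0.02, "CO2+H2O" = 0.03,
                      "2CO2+H2O" = 0.09, "CH3OH" = 0, "CO2+CH3OH" = 0,
                      "2CO2+CH3OH" = 0),
    btca_isomer_3 = c(precursor = 0.45, "CO2" = 0.30, "2CO2" = 0.05,
                      "3CO2" = 0.02, "H2O" = 0.12, "CO2+H2O" = 0.05,
                      "2CO2+H2O" = 0.01, "CH3OH" = 0, "CO2+CH3OH" = 0,
                      "2CO2+CH3OH" = 0)
  )
  losses <- neutral_loss_table()
  loss_mass <- setNames(losses$exact_mass, losses$label)
  pmz <- ion_mass("C9H6O6")
  purrr::map_dfr(names(prof), function(id) {
    p <- prof[[id]]
    p <- p[p > 0]
    mz <- ifelse(names(p) == "precursor", pmz, pmz - loss_mass[names(p)])
    peaklist(tibble(mz = mz, intensity = 1000 * as.numeric(p),
                    snr = 1000 * as.numeric(p) / 0.2, sample_id = id))
  })
}
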