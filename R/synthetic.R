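#' Configuration for the synthetic-data generators
#'
#' Bundles the ground-truth parameters used by [gen_variant_panel()],
#' [gen_turbidity_panel()], [gen_tht_panel()] and [gen_sec()]. Defaults
#' emulate the study conditions the pipeline targets: a panel of loop-motif
#' variants spanning polar-to-hydrophobic motifs, turbidity assays cycled
#' every 90 s, thioflavin-T panels at chaperone molar ratios 0/10/50/100%
#' with 3 umol/L substrate monomer and four replicates, and large
#' polydisperse oligomers of roughly 18-30 subunits on SEC.
#'
#' @param seed Mandatory integer seed; every generator is fully
#'   deterministic given the config.
#' @param n_variants Number of motif variants in the panel (>= 3).
#' @param true_slope,true_intercept Ground-truth linear activity model:
#'   `mass_pct = clamp(intercept + slope * hydropathy + noise, 0, 100)`
#'   (hydropathy on the larger-is-more-hydrophobic orientation, so the
#'   slope is negative: more hydrophobic motifs suppress aggregation more).
#' @param noise_sd_pct Gaussian noise sd on the true activities, percent.
#' @param turbidity_noise Additive Gaussian noise sd on turbidity traces,
#'   AU (instrument-like).
#' @param turbidity_replicates Replicates per turbidity condition.
#' @param kinetics Baseline [kinetic_params()] for the thioflavin-T panel.
#' @param suppression_target Which rate constant the simulated chaperone
#'   suppresses: `"k_2"`, `"k_plus"` or `"k_n"`.
#' @param suppression_factors Named per-ratio multiplicative factors on the
#'   suppressed constant (names are ratio percentages; must include `"0"`
#'   with factor 1).
#' @param tht_noise_frac Multiplicative Gaussian noise sd on thioflavin-T
#'   fluorescence (fluorescence-like), fraction.
#' @param tht_F0,tht_A Fluorescence baseline and amplitude, AU.
#' @param tht_duration,tht_cycle Thioflavin-T time span and cycle, seconds.
#' @param sec_monomer_mw Monomer molecular weight for the SEC generator, Da.
#' @param sec_subunits_peak,sec_subunits_range Ground-truth oligomer size:
#'   peak subunit count and FWHM range `(lo, hi)`.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_variants = 10L,
                             true_slope = -3,
                             true_intercept = 40,
                             noise_sd_pct = 5,
                             turbidity_noise = 0.01,
                             turbidity_replicates = 3L,
                             kinetics = kinetic_params_lk(
                               lambda = 4e-5, kappa = 1.2e-3),
                             suppression_target = "k_2",
                             suppression_factors = c(
                               "0" = 1, "10" = 0.5, "50" = 0.2, "100" = 0.1),
                             tht_noise_frac = 0.02,
                             tht_F0 = 50, tht_A = 950,
                             tht_duration = 43200, tht_cycle = 360,
                             sec_monomer_mw = 13300,
                             sec_subunits_peak = 24L,
                             sec_subunits_range = c(18L, 30L)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_variants >= 3L, noise_sd_pct >= 0, turbidity_noise >= 0,
            tht_noise_frac >= 0, inherits(kinetics, "kinetic_params"),
            suppression_target %in% c("k_2", "k_plus", "k_n"),
            "0" %in% names(suppression_factors),
            all(suppression_factors > 0))
  structure(
    list(seed = as.integer(seed), n_variants = as.integer(n_variants),
         true_slope = true_slope, true_intercept = true_intercept,
         noise_sd_pct = noise_sd_pct, turbidity_noise = turbidity_noise,
         turbidity_replicates = as.integer(turbidity_replicates),
         kinetics = kinetics, suppression_target = suppression_target,
         suppression_factors = suppression_factors,
         tht_noise_frac = tht_noise_frac, tht_F0 = tht_F0, tht_A = tht_A,
         tht_duration = tht_duration, tht_cycle = tht_cycle,
         sec_monomer_mw = sec_monomer_mw,
         sec_subunits_peak = as.integer(sec_subunits_peak),
         sec_subunits_range = as.integer(sec_subunits_range)),
    class = "generator_config")
}

#' Generate a loop-motif variant panel with known activities
#'
#' Builds a panel of synthetic motif sets spanning a wide hydropathy range
#' and assigns each variant a ground-truth activity from the linear model in
#' the config. The panel always contains, by construction: a hydrophobic
#' wild-type-like variant, an all-EGR polar variant (the classic
#' motif-inactivating substitution), a serine/alanine-softened variant, and
#' an anchor Thr-to-Trp swap of the wild-type-like variant; remaining slots
#' are random tripeptide variants.
#'
#' @param cfg A [generator_config()].
#' @param scale A [load_scale()] object used to compute the ground-truth
#'   hydropathy scores.
#' @return List with `motifs` (data frame: `variant_id`, `motif1..3`,
#'   `anchor206`), `truth` (data frame: `variant_id`, `combined` score,
#'   `activity` = true mean mass_pct before noise, `activity_noisy` =
#'   clamped noisy activity used downstream).
#' @export
gen_variant_panel <- function(cfg, scale) {
  stopifnot(inherits(cfg, "generator_config"),
            inherits(scale, "hydropathy_scale"))
  .with_seed(cfg$seed, {
    designed <- list(
      motif_set("wt_like",   "FII", "LIV", "VFA", "T"),
      motif_set("egr_all",   "EGR", "EGR", "EGR", "T"),
      motif_set("sas_soft",  "SAS", "SSA", "SAS", "T"),
      motif_set("anchor_trp", "FII", "LIV", "VFA", "W")
    )
    n_random <- max(cfg$n_variants - length(designed), 0L)
    randoms <- lapply(seq_len(n_random), function(i) {
      motif_set(sprintf("rnd_%02d", i),
                paste(sample(AA_STANDARD, 3, replace = TRUE), collapse = ""),
                paste(sample(AA_STANDARD, 3, replace = TRUE), collapse = ""),
                paste(sample(AA_STANDARD, 3, replace = TRUE), collapse = ""),
                sample(c("T", "W", "S"), 1))
    })
    panel <- c(designed, randoms)[seq_len(max(cfg$n_variants, 4L))]
    scores <- score_panel(panel, scale)
    activity <- cfg$true_intercept + cfg$true_slope * scores$combined
    noisy <- activity + stats::rnorm(length(activity), 0, cfg$noise_sd_pct)
    noisy <- pmin(pmax(noisy, 0), 100)
    motifs <- do.call(rbind, lapply(panel, function(m)
      data.frame(variant_id = m$variant_id, motif1 = m$motif1,
                 motif2 = m$motif2, motif3 = m$motif3,
                 anchor206 = m$anchor206, stringsAsFactors = FALSE)))
    list(motifs = motifs,
         truth = data.frame(variant_id = scores$variant_id,
                            combined = scores$combined,
                            activity = pmin(pmax(activity, 0), 100),
                            activity_noisy = noisy,
                            stringsAsFactors = FALSE))
  })
}

# unit-amplitude logistic turbidity shape on a 90 s grid
.turbidity_shape <- function(times) 1 / (1 + exp((1800 - times) / 300))

#' Generate a turbidity plate from known activities
#'
#' Emits a long-form plate table (`time_s`, `well`, `signal`) and well map
#' emulating a 90 s-cycle absorbance assay: the substrate-alone control is
#' a saturating logistic, and each variant's trace is the control shape
#' scaled by `activity/100` (so the expected AUC ratio *is* the activity),
#' plus additive Gaussian instrument noise on every read.
#'
#' @param cfg A [generator_config()].
#' @param activities Data frame with `variant_id` and `activity_noisy` (or
#'   `activity`) in `[0, 100]`, e.g. the `truth` of [gen_variant_panel()].
#' @param ratio Ratio label stored in the well map (default `"1:1"`).
#' @return List with `plate` (long-form data frame) and `map` (well map
#'   data frame with columns `well`, `substrate`, `chaperone`, `ratio`,
#'   `replicate`).
#' @export
gen_turbidity_panel <- function(cfg, activities, ratio = "1:1") {
  stopifnot(inherits(cfg, "generator_config"))
  act <- if ("activity_noisy" %in% names(activities))
    activities$activity_noisy else activities$activity
  stopifnot(all(act >= 0 & act <= 100))
  times <- seq(0, 5400, by = 90)
  shape <- .turbidity_shape(times)
  .with_seed(cfg$seed + 1L, {
    conds <- rbind(
      data.frame(chaperone = NA_character_, level = 1,
                 stringsAsFactors = FALSE),
      data.frame(chaperone = activities$variant_id, level = act / 100,
                 stringsAsFactors = FALSE))
    plate <- list(); map <- list(); w <- 0L
    for (i in seq_len(nrow(conds))) {
      for (rep in seq_len(cfg$turbidity_replicates)) {
        w <- w + 1L
        well <- sprintf("W%03d", w)
        sig <- conds$level[i] * shape +
          stats::rnorm(length(times), 0, cfg$turbidity_noise)
        plate[[w]] <- data.frame(time_s = times, well = well, signal = sig,
                                 stringsAsFactors = FALSE)
        map[[w]] <- data.frame(well = well, substrate = "CS",
                               chaperone = conds$chaperone[i],
                               ratio = ratio, replicate = rep,
                               stringsAsFactors = FALSE)
      }
    }
    list(plate = do.call(rbind, plate), map = do.call(rbind, map))
  })
}

#' Generate a thioflavin-T dilution panel with known kinetics
#'
#' Simulates fibril-formation fluorescence panels at chaperone molar ratios
#' given by the config's suppression factors: each condition's curve is the
#' closed-form mass fraction with the targeted rate constant multiplied by
#' the per-ratio factor, scaled to fluorescence (`F0 + A * M/M_inf`) with
#' multiplicative Gaussian noise, four replicates per condition.
#'
#' @param cfg A [generator_config()].
#' @param n_replicates Replicates per ratio (default 4).
#' @return List with `plate` (long form), `map` (well map; `ratio` column
#'   holds the molar percentage), and `truth` (per-ratio factors, effective
#'   [kinetic_params()] and closed-form half-times).
#' @export
gen_tht_panel <- function(cfg, n_replicates = 4L) {
  stopifnot(inherits(cfg, "generator_config"))
  times <- seq(0, cfg$tht_duration, by = cfg$tht_cycle)
  base <- cfg$kinetics
  ratios <- names(cfg$suppression_factors)
  eff_params <- lapply(cfg$suppression_factors, function(f) {
    k <- list(k_n = base$k_n, k_plus = base$k_plus, k_2 = base$k_2)
    k[[cfg$suppression_target]] <- k[[cfg$suppression_target]] * f
    kinetic_params(k$k_n, k$k_plus, k$k_2, n_C = base$n_C, n_2 = base$n_2,
                   m0 = base$m0)
  })
  .with_seed(cfg$seed + 2L, {
    plate <- list(); map <- list(); w <- 0L
    for (r in ratios) {
      m <- simulate_mass_fraction(eff_params[[r]], times)
      for (rep in seq_len(n_replicates)) {
        w <- w + 1L
        well <- sprintf("T%03d", w)
        sig <- (cfg$tht_F0 + cfg$tht_A * m) *
          (1 + stats::rnorm(length(times), 0, cfg$tht_noise_frac))
        plate[[w]] <- data.frame(time_s = times, well = well, signal = sig,
                                 stringsAsFactors = FALSE)
        map[[w]] <- data.frame(well = well, substrate = "Abeta42",
                               chaperone = if (r == "0") NA_character_
                                           else "chaperone",
                               ratio = r, replicate = rep,
                               stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(
      ratio_pct = as.numeric(ratios),
      factor = unname(cfg$suppression_factors),
      target = cfg$suppression_target,
      tau_half_s = vapply(eff_params, mass_fraction_halftime, numeric(1)),
      stringsAsFactors = FALSE)
    list(plate = do.call(rbind, plate), map = do.call(rbind, map),
         truth = truth, params = eff_params)
  })
}

#' Generate an SEC chromatogram, calibration and ground truth
#'
#' Builds a log-linear column calibration, a set of calibration standards
#' lying exactly on it, and a peak placed so that its maximum corresponds to
#' the configured subunit count and its half-height crossings to the
#' configured FWHM subunit range (the peak is piecewise-Gaussian, with
#' independent left/right widths, so both crossings land exactly where
#' specified). Small Gaussian noise is added to the absorbance away from
#' the peak region.
#'
#' @param cfg A [generator_config()].
#' @param cal_intercept,cal_slope Calibration line `log10(MW) = a + b * v`
#'   (defaults: MW 1e6 Da at 8 mL, one decade per 4 mL).
#' @param noise_sd Absorbance noise sd (default 1e-3).
#' @return List with `chromatogram` (data frame `elution_volume`, `a280`),
#'   `standards` (data frame for [sec_calibration()]), `calibration`, and
#'   `truth` (subunit peak/range and their volumes).
#' @export
gen_sec <- function(cfg, cal_intercept = 8, cal_slope = -0.25,
                    noise_sd = 1e-3) {
  stopifnot(inherits(cfg, "generator_config"), cal_slope < 0)
  v_of_mw <- function(mw) (log10(mw) - cal_intercept) / cal_slope
  mw <- cfg$sec_monomer_mw
  v_pk <- v_of_mw(mw * cfg$sec_subunits_peak)
  v_hi_mw <- v_of_mw(mw * cfg$sec_subunits_range[2L])  # earlier volume
  v_lo_mw <- v_of_mw(mw * cfg$sec_subunits_range[1L])  # later volume
  stopifnot(v_hi_mw < v_pk, v_pk < v_lo_mw)
  hwhm_l <- v_pk - v_hi_mw
  hwhm_r <- v_lo_mw - v_pk
  s_l <- hwhm_l / sqrt(2 * log(2))
  s_r <- hwhm_r / sqrt(2 * log(2))
  vols <- seq(v_pk - 6 * hwhm_l, v_pk + 6 * hwhm_r, length.out = 400)
  a280 <- ifelse(vols <= v_pk,
                 exp(-(vols - v_pk)^2 / (2 * s_l^2)),
                 exp(-(vols - v_pk)^2 / (2 * s_r^2)))
  .with_seed(cfg$seed + 3L, {
    core <- abs(vols - v_pk) < 1.5 * pmax(hwhm_l, hwhm_r)
    a280[!core] <- a280[!core] + stats::rnorm(sum(!core), 0, noise_sd)
    std_mw <- c(669e3, 440e3, 158e3, 44e3, 17e3)
    standards <- data.frame(elution_volume = v_of_mw(std_mw),
                            molecular_weight = std_mw)
    list(chromatogram = data.frame(elution_volume = vols, a280 = a280),
         standards = standards,
         calibration = sec_calibration(standards),
         truth = list(subunits_peak = cfg$sec_subunits_peak,
                      subunits_range = cfg$sec_subunits_range,
                      peak_volume = v_pk,
                      fwhm_volumes = c(v_hi_mw, v_lo_mw)))
  })
}

#' Write a generated plate to disk
#'
#' Writes the exact CSV/TSV dialects the readers consume: a long-form plate
#' CSV and a well-map TSV.
#'
#' @param panel A list with `plate` and `map` (from [gen_turbidity_panel()]
#'   or [gen_tht_panel()]).
#' @param traces_csv,map_tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_plate <- function(panel, traces_csv, map_tsv) {
  utils::write.csv(panel$plate, traces_csv, row.names = FALSE)
  write_tsv(panel$map, map_tsv)
  invisible(c(traces_csv, map_tsv))
}

# minimal TSV writer (NA -> empty cell, no quoting surprises)
write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
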