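test_that("generators are fully deterministic under a fixed seed", {
  bio <- load_scale("biological")
  cfg <- generator_config(seed = 42)
  expect_identical(gen_variant_panel(cfg, bio), gen_variant_panel(cfg, bio))
  vp <- gen_variant_panel(cfg, bio)
  expect_identical(gen_turbidity_panel(cfg, vp$truth),
                   gen_turbidity_panel(cfg, vp$truth))
  expect_identical(gen_tht_panel(cfg)$plate, gen_tht_panel(cfg)$plate)
  expect_identical(gen_sec(cfg)$chromatogram, gen_sec(cfg)$chromatogram)
  # a different seed changes the draws
  cfg2 <- generator_config(seed = 43)
  expect_false(identical(gen_variant_panel(cfg2, bio), vp))
  # generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(gen_tht_panel(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("variant panels span hydropathy and honour the linear ground truth", {
  bio <- load_scale("biological")
  cfg <- generator_config(seed = 7, noise_sd_pct = 0)
  vp <- gen_variant_panel(cfg, bio)
  expect_equal(nrow(vp$motifs), cfg$n_variants)
  expect_true(all(c("wt_like", "egr_all", "sas_soft", "anchor_trp") %in%
                  vp$motifs$variant_id))
  rescored <- score_panel(vp$motifs, bio)
  expect_equal(rescored$combined, vp$truth$combined)
  # zero noise: activities sit exactly on the clamped line
  expect_equal(vp$truth$activity_noisy,
               pmin(pmax(cfg$true_intercept +
                           cfg$true_slope * vp$truth$combined, 0), 100))
  # flipping the slope sign flips the fitted slope sign downstream
  cfg_flip <- generator_config(seed = 7, noise_sd_pct = 0, true_slope = 3,
                               true_intercept = 20)
  vp_flip <- gen_variant_panel(cfg_flip, bio)
  interior <- function(tr) tr$activity_noisy > 0 & tr$activity_noisy < 100
  k1 <- interior(vp$truth); k2 <- interior(vp_flip$truth)
  expect_lt(cor(vp$truth$combined[k1], vp$truth$activity_noisy[k1]), 0)
  expect_gt(cor(vp_flip$truth$combined[k2],
                vp_flip$truth$activity_noisy[k2]), 0)
})

test_that("turbidity panels encode activity as the AUC ratio", {
  cfg <- generator_config(seed = 19, turbidity_noise = 0.005)
  acts <- data.frame(variant_id = c("full", "none"),
                     activity_noisy = c(100, 0))
  tp <- gen_turbidity_panel(cfg, acts)
  traces <- traces_from_plate(tp$plate, tp$map)
  tab <- aggregation_mass_panel(traces)
  # activity 100 -> indistinguishable from control within noise
  expect_equal(tab$mass_pct[match("full", tab$variant_id)], 100,
               tolerance = 0.05)
  # activity 0 -> flat traces
  expect_equal(tab$mass_pct[match("none", tab$variant_id)], 0,
               tolerance = 5)  # percent, absolute noise floor
  # full round trip at moderate noise recovers activities within 2 sd
  cfgN <- generator_config(seed = 23, noise_sd_pct = 4)
  vp <- gen_variant_panel(cfgN, load_scale("biological"))
  tpN <- gen_turbidity_panel(cfgN, vp$truth)
  tabN <- aggregation_mass_panel(traces_from_plate(tpN$plate, tpN$map))
  merged <- merge(tabN, vp$truth, by = "variant_id")
  expect_true(all(abs(merged$mass_pct - merged$activity_noisy) < 2))
})

test_that("thioflavin-T panels carry the configured kinetic ground truth", {
  cfg <- generator_config(seed = 29, suppression_factors = c("0" = 1,
                                                             "100" = 1))
  tp <- gen_tht_panel(cfg)
  # suppression factors all 1: both ratios share one underlying curve
  m0 <- tp$plate[tp$plate$well == "T001", "signal"]
  expect_equal(tp$truth$tau_half_s[1], tp$truth$tau_half_s[2])
  # halving kappa (via k_2 factor) delays the half-time
  cfg2 <- generator_config(seed = 29,
                           suppression_factors = c("0" = 1, "100" = 0.25))
  tr2 <- gen_tht_panel(cfg2)$truth
  expect_gt(tr2$tau_half_s[tr2$ratio_pct == 100],
            tr2$tau_half_s[tr2$ratio_pct == 0])
})

test_that("generated plates round-trip losslessly through the file readers", {
  cfg <- generator_config(seed = 37, n_variants = 3)
  vp <- gen_variant_panel(cfg, load_scale("biological"))
  tp <- gen_turbidity_panel(cfg, vp$truth)
  traces_csv <- withr::local_tempfile(fileext = ".csv")
  map_tsv <- withr::local_tempfile(fileext = ".tsv")
  write_plate(tp, traces_csv, map_tsv)
  from_file <- read_plate(traces_csv, map_tsv)
  from_mem <- traces_from_plate(tp$plate, tp$map)
  expect_equal(names(from_file), names(from_mem))
  for (w in names(from_mem)) {
    expect_equal(from_file[[w]]$signal, from_mem[[w]]$signal)
    expect_equal(from_file[[w]]$chaperone, from_mem[[w]]$chaperone)
    expect_equal(from_file[[w]]$ratio, from_mem[[w]]$ratio)
  }
})

test_that("config validation catches impossible settings", {
  expect_error(generator_config(), "seed")
  expect_error(generator_config(seed = 1, n_variants = 2), "n_variants")
  expect_error(generator_config(seed = 1, noise_sd_pct = -1))
  expect_error(generator_config(seed = 1,
                                suppression_factors = c("10" = 0.5)))
})
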