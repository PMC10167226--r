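write_amorphous_inputs <- function(dir, seed = 77, noise_sd_pct = 0,
                                   turbidity_noise = 0) {
  cfg <- generator_config(seed = seed, noise_sd_pct = noise_sd_pct,
                          turbidity_noise = turbidity_noise)
  bio <- load_scale("biological")
  vp <- gen_variant_panel(cfg, bio)
  tp <- gen_turbidity_panel(cfg, vp$truth)
  paths <- list(motifs = file.path(dir, "motifs.tsv"),
                traces = file.path(dir, "plate.csv"),
                map = file.path(dir, "wells.tsv"),
                out_dir = file.path(dir, "out"))
  utils::write.table(vp$motifs, paths$motifs, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  write_plate(tp, paths$traces, paths$map)
  list(paths = paths, truth = vp$truth)
}

test_that("the amorphous workflow recovers a zero-noise ground truth end to end", {
  dir <- withr::local_tempdir()
  inp <- write_amorphous_inputs(dir)
  cfg <- c(inp$paths, list(predict_motifs = inp$paths$motifs))
  res <- run_amorphous(cfg)
  # noiseless panel: R^2 = 1 and predictions equal the true activities
  expect_equal(res$model$r_squared, 1, tolerance = 1e-6)
  merged <- merge(res$predictions, inp$truth, by = "variant_id")
  expect_equal(merged$fit, merged$activity, tolerance = 1e-3)
  # outputs and manifest exist, and the manifest hashes match the files
  for (f in c("scores.tsv", "masses.tsv", "model.json", "predictions.tsv",
              "manifest.json")) {
    expect_true(file.exists(file.path(inp$paths$out_dir, f)))
  }
  man <- jsonlite::read_json(file.path(inp$paths$out_dir, "manifest.json"))
  for (f in names(man$files)) {
    expect_equal(unname(tools::md5sum(file.path(inp$paths$out_dir, f))),
                 man$files[[f]])
  }
})

test_that("reruns on the same inputs are byte-identical apart from the manifest timestamp", {
  dir <- withr::local_tempdir()
  inp <- write_amorphous_inputs(dir, seed = 78, noise_sd_pct = 3,
                                turbidity_noise = 0.01)
  cfg1 <- c(inp$paths, list())
  cfg2 <- inp$paths; cfg2$out_dir <- file.path(dir, "out2")
  run_amorphous(cfg1); run_amorphous(cfg2)
  for (f in c("scores.tsv", "masses.tsv", "model.json")) {
    expect_identical(readLines(file.path(inp$paths$out_dir, f)),
                     readLines(file.path(cfg2$out_dir, f)))
  }
})

test_that("stage failures carry the stage name", {
  dir <- withr::local_tempdir()
  inp <- write_amorphous_inputs(dir, seed = 79)
  bad <- inp$paths
  bad$map <- file.path(dir, "missing.tsv")
  expect_error(run_amorphous(bad), "does not exist")
  expect_error(run_amorphous(inp$paths[c("motifs", "traces")]),
               "stage config")
})

test_that("the amyloid workflow identifies the suppressed constant and is reproducible", {
  dir <- withr::local_tempdir()
  gcfg <- generator_config(seed = 55,
                           suppression_factors = c("0" = 1, "100" = 0.1),
                           tht_cycle = 720)
  tp <- gen_tht_panel(gcfg)
  paths <- list(traces = file.path(dir, "tht.csv"),
                map = file.path(dir, "tht_wells.tsv"),
                out_dir = file.path(dir, "amyloid"))
  write_plate(tp, paths$traces, paths$map)
  cfg <- c(paths, list(n_starts = 4L, seed = 55L))
  res <- run_amyloid(cfg)
  expect_equal(res$ranking[[1]]$free_constant, "k_2")
  # half-time delay direction matches the generated suppression
  expect_gt(res$delays$delay[res$delays$ratio_pct == 100], 1)
  expect_equal(res$delays$delay[res$delays$ratio_pct == 0], 1)
  # deterministic rerun: identical fitted values
  cfg2 <- cfg; cfg2$out_dir <- file.path(dir, "amyloid2")
  res2 <- run_amyloid(cfg2)
  expect_identical(readLines(file.path(paths$out_dir, "global_fits.json")),
                   readLines(file.path(cfg2$out_dir, "global_fits.json")))
  expect_error(run_amyloid(list(traces = paths$traces, out_dir = dir)),
               "stage config")
})

test_that("config files load from YAML and JSON with defaults applied", {
  dir <- withr::local_tempdir()
  yml <- file.path(dir, "run.yaml")
  writeLines(c("seed: 9", "baseline_n: 5"), yml)
  cfg <- read_run_config(yml)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$baseline_n, 5)
  expect_equal(cfg$scale, "biological")   # default surfaced
  expect_equal(cfg$m0, 3e-6)
  js <- file.path(dir, "run.json")
  writeLines('{"seed": 9, "baseline_n": 5}', js)
  expect_equal(read_run_config(js)$baseline_n, 5)
  expect_error(read_run_config(file.path(dir, "nope.yaml")), "not found")
  expect_error(run_config(list(motifs = file.path(dir, "ghost.tsv"))),
               "does not exist")
})
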