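#' Read a run configuration
#'
#' Loads a YAML or JSON run configuration for [run_amorphous()] /
#' [run_amyloid()]. All tunable defaults are surfaced in the config rather
#' than buried in code: `baseline_n` (3), `scale` (`"biological"`),
#' `ci_level` (0.95), `m0` (3e-6 mol/L), `n_C`/`n_2` (2), `free_constants`
#' (all three candidates), `seed` (1).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of configuration entries.
#' @export
run_config <- function(cfg) {
  defaults <- list(baseline_n = 3L, scale = "biological", ci_level = 0.95,
                   m0 = 3e-6, n_C = 2, n_2 = 2,
                   free_constants = c("k_2", "k_plus", "k_n"),
                   n_starts = 16L, seed = 1L, clamp_predictions = TRUE)
  cfg <- utils::modifyList(defaults, cfg)
  for (f in c("motifs", "traces", "map", "predict_motifs")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config error: referenced file does not exist: ", cfg[[f]],
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

# write a manifest listing every output with its md5, plus provenance
.write_manifest <- function(out_dir, files, seed) {
  manifest <- list(
    package = "loopchap",
    version = as.character(utils::packageVersion("loopchap")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# wrap stage errors with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the amorphous-aggregation activity workflow
#'
#' End-to-end composition: motif hydropathy scoring, aggregation-mass
#' quantification of the turbidity plate, the hydropathy–activity
#' regression, and (optionally) activity predictions for new motif sets.
#' Writes `scores.tsv`, `masses.tsv`, `model.json`, `predictions.tsv` (when
#' requested) and a `manifest.json` with an md5 for every output, into
#' `cfg$out_dir`.
#'
#' Required config entries: `motifs` (motif TSV), `traces` (plate CSV),
#' `map` (well-map TSV), `out_dir`; optional: `ratio`, `predict_motifs`,
#' plus the defaults listed under [read_run_config()].
#'
#' @param cfg A [run_config()] (or plain named list).
#' @return Invisibly, a list with `scores`, `masses`, `model`,
#'   `predictions` (or `NULL`) and the manifest.
#' @export
run_amorphous <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  for (f in c("motifs", "traces", "map", "out_dir")) {
    if (is.null(cfg[[f]])) {
      stop("[stage config] missing required entry: ", f, call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  scale <- .stage("scale", load_scale(cfg$scale))
  scores <- .stage("hydropathy",
                   score_panel(read_motif_table(cfg$motifs), scale))
  traces <- .stage("plate", read_plate(cfg$traces, cfg$map))
  masses <- .stage("aggmass",
                   aggregation_mass_panel(traces, baseline_n = cfg$baseline_n))
  model <- .stage("regression",
                  fit_activity_regression(scores, masses, ratio = cfg$ratio))
  predictions <- NULL
  if (!is.null(cfg$predict_motifs)) {
    predictions <- .stage("predict", {
      new_scores <- score_panel(read_motif_table(cfg$predict_motifs), scale)
      predict(model, new_scores, level = cfg$ci_level,
              clamp = cfg$clamp_predictions)
    })
  }
  write_tsv(scores, file.path(cfg$out_dir, "scores.tsv"))
  write_tsv(masses, file.path(cfg$out_dir, "masses.tsv"))
  jsonlite::write_json(
    model[c("slope", "intercept", "r_squared", "p_value", "residual_sd",
            "n", "x_mean", "x_sumsq", "x_scale_name", "ratio")],
    file.path(cfg$out_dir, "model.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  files <- c("scores.tsv", "masses.tsv", "model.json")
  if (!is.null(predictions)) {
    write_tsv(predictions, file.path(cfg$out_dir, "predictions.tsv"))
    files <- c(files, "predictions.tsv")
  }
  manifest <- .write_manifest(cfg$out_dir, files, cfg$seed)
  invisible(list(scores = scores, masses = masses, model = model,
                 predictions = predictions, manifest = manifest))
}

#' Run the amyloid-kinetics workflow
#'
#' End-to-end composition for a thioflavin-T dilution panel: per-ratio
#' replicate normalization and averaging, empirical sigmoid fits and the
#' half-time delay table, and the constrained global rate-law fits for each
#' candidate free rate constant, ranked by residual sum of squares. Writes
#' `sigmoid_fits.tsv`, `halftime_delay.tsv`, `global_fits.json` and
#' `manifest.json` into `cfg$out_dir`.
#'
#' Required config entries: `traces`, `map`, `out_dir`; optional: `m0`,
#' `n_C`, `n_2`, `free_constants`, `n_starts`, `seed`.
#'
#' @param cfg A [run_config()] (or plain named list).
#' @return Invisibly, a list with `normalized` (per-ratio curves), `fits`
#'   (per-ratio [fit_sigmoid()]s), `delays`, `ranking`
#'   (a `global_fit_ranking`) and the manifest.
#' @export
run_amyloid <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  for (f in c("traces", "map", "out_dir")) {
    if (is.null(cfg[[f]])) {
      stop("[stage config] missing required entry: ", f, call. = FALSE)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  traces <- .stage("plate", read_plate(cfg$traces, cfg$map))
  ratios <- vapply(traces, function(x) as.character(x$ratio), character(1))
  if (!"0" %in% ratios) {
    stop("[stage panel] control ratio '0' absent", call. = FALSE)
  }
  panel <- .stage("normalize", normalize_panel(traces))
  fits <- .stage("sigmoid", lapply(panel, function(p)
    fit_sigmoid(aggregation_trace(p$times, p$mean))))
  delays <- .stage("halftime", halftime_delay(fits))
  ranking <- .stage("globalfit", {
    fits3 <- lapply(cfg$free_constants, function(fc)
      global_fit(panel, fc, m0 = cfg$m0, n_C = cfg$n_C, n_2 = cfg$n_2,
                 n_starts = cfg$n_starts, seed = cfg$seed))
    fits3 <- fits3[order(vapply(fits3, `[[`, numeric(1),
                                "residual_sum_squares"))]
    structure(fits3, class = "global_fit_ranking")
  })
  sig_tab <- do.call(rbind, lapply(names(fits), function(r)
    data.frame(ratio_pct = as.numeric(r), t(coef(fits[[r]])))))
  write_tsv(sig_tab, file.path(cfg$out_dir, "sigmoid_fits.tsv"))
  write_tsv(delays, file.path(cfg$out_dir, "halftime_delay.tsv"))
  jsonlite::write_json(
    lapply(ranking, function(g)
      g[c("free_constant", "lambda", "kappa", "k_plus_k_n", "k_plus_k_2",
          "per_condition", "residual_sum_squares", "seed", "degenerate")]),
    file.path(cfg$out_dir, "global_fits.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)
  manifest <- .write_manifest(
    cfg$out_dir, c("sigmoid_fits.tsv", "halftime_delay.tsv",
                   "global_fits.json"), cfg$seed)
  invisible(list(normalized = panel, fits = fits, delays = delays,
                 ranking = ranking, manifest = manifest))
}
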