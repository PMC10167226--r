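# shared fixture builders (all fixtures are generated in code)

# noiseless empirical sigmoid on a grid
logistic_signal <- function(times, F0 = 0, A = 1, r_max = 1e-3,
                            tau = NULL) {
  if (is.null(tau)) tau <- stats::median(times)
  F0 + A / (1 + exp(r_max * (tau - times)))
}

# a generated thioflavin-T panel together with its normalized per-ratio
# curves, ready for global_fit()
make_tht_panel <- function(seed, ...) {
  cfg <- generator_config(seed = seed, ...)
  tp <- gen_tht_panel(cfg)
  traces <- traces_from_plate(tp$plate, tp$map)
  list(cfg = cfg, truth = tp$truth, plate = tp$plate, map = tp$map,
       panel = normalize_panel(traces))
}

# turbidity replicate traces for a given suppression level of the control
# shape (level = activity/100), optionally noisy
turbidity_traces <- function(level, n_rep = 3, noise = 0, seed = 1,
                             chaperone = NA_character_, ratio = "1:1") {
  times <- seq(0, 5400, by = 90)
  shape <- 1 / (1 + exp((1800 - times) / 300))
  set.seed(seed)
  lapply(seq_len(n_rep), function(r) {
    aggregation_trace(times, level * shape + rnorm(length(times), 0, noise),
                      substrate = "CS", chaperone = chaperone,
                      ratio = ratio, replicate = r)
  })
}
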