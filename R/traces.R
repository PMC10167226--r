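#' Construct an aggregation trace
#'
#' One time-resolved aggregation measurement: turbidity (absorbance at
#' 360 nm) for amorphous aggregation of heat-destabilized substrates, or
#' thioflavin-T fluorescence for amyloid formation.
#'
#' @param times Time points in seconds, strictly increasing, at least 4.
#' @param signal Signal values (absorbance or fluorescence, AU), finite,
#'   same length as `times`.
#' @param substrate Substrate identifier (e.g. `"CS"`, `"Rho"`, `"Abeta42"`).
#' @param chaperone Chaperone variant id, or `NA` for the substrate-alone
#'   control.
#' @param ratio Substrate:chaperone molar ratio label (monomer-subunit
#'   basis), e.g. `"1:1"`, or for thioflavin-T panels the chaperone molar
#'   percentage (0, 10, 50, 100).
#' @param replicate Replicate index.
#' @param temperature Incubation temperature, degrees C.
#' @return An object of class `aggregation_trace`.
#' @export
aggregation_trace <- function(times, signal, substrate = NA_character_,
                              chaperone = NA_character_, ratio = NA,
                              replicate = 1L, temperature = NA_real_) {
  times <- as.numeric(times)
  signal <- as.numeric(signal)
  if (length(times) < 4L) stop("need at least 4 time points", call. = FALSE)
  if (length(times) != length(signal)) {
    stop("times and signal lengths differ", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(signal))) stop("non-finite signal", call. = FALSE)
  structure(
    list(times = times, signal = signal, substrate = substrate,
         chaperone = chaperone, ratio = ratio,
         replicate = as.integer(replicate), temperature = temperature),
    class = "aggregation_trace"
  )
}

#' @export
print.aggregation_trace <- function(x, ...) {
  cat(sprintf(
    "Aggregation trace: %d points over [%g, %g] s | substrate %s | %s | rep %d\n",
    length(x$times), min(x$times), max(x$times), x$substrate,
    if (is.na(x$chaperone)) "no chaperone"
    else sprintf("chaperone %s (ratio %s)", x$chaperone, x$ratio),
    x$replicate))
  invisible(x)
}

#' Baseline-correct a trace
#'
#' Subtracts the mean of the first `n_initial` signal values. Negative
#' corrected values are retained, not clipped, so that noise around the
#' baseline does not bias downstream areas under the curve.
#'
#' @param trace An [aggregation_trace()].
#' @param n_initial Number of initial points to average (default 3).
#' @return The corrected `aggregation_trace`.
#' @export
baseline_correct <- function(trace, n_initial = 3L) {
  stopifnot(inherits(trace, "aggregation_trace"))
  n_initial <- as.integer(n_initial)
  if (n_initial < 1L || n_initial >= length(trace$times)) {
    stop("n_initial must be >= 1 and < number of points", call. = FALSE)
  }
  trace$signal <- trace$signal - mean(trace$signal[seq_len(n_initial)])
  trace
}

#' Read plate-reader kinetics with a well map
#'
#' Reads a plate-reader CSV and a well-map TSV into a list of
#' [aggregation_trace()] objects. Two CSV dialects are accepted:
#'
#' * long form: columns `time_s`, `well`, `signal`;
#' * wide form: a `time_s` column followed by one column per well.
#'
#' The well map is a TSV with columns `well`, `substrate`, `chaperone`,
#' `ratio`, `replicate` (empty/`NA` chaperone marks substrate-alone control
#' wells). Wells absent from the map are dropped with a warning.
#'
#' @param traces_csv Path to the plate CSV.
#' @param map_tsv Path to the well-map TSV.
#' @param temperature Optional temperature annotation, degrees C.
#' @return A list of `aggregation_trace` objects, one per mapped well.
#' @export
read_plate <- function(traces_csv, map_tsv, temperature = NA_real_) {
  raw <- utils::read.csv(traces_csv, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"time_s" %in% names(raw)) {
    stop("plate CSV must contain a 'time_s' column", call. = FALSE)
  }
  if (all(c("well", "signal") %in% names(raw))) {  # long form
    long <- raw[, c("time_s", "well", "signal")]
  } else {                                         # wide form
    wells <- setdiff(names(raw), "time_s")
    long <- do.call(rbind, lapply(wells, function(w) {
      data.frame(time_s = raw$time_s, well = w, signal = raw[[w]],
                 stringsAsFactors = FALSE)
    }))
  }
  map <- utils::read.delim(map_tsv, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = c("", "NA"))
  need <- c("well", "substrate", "chaperone", "ratio", "replicate")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("well map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  traces_from_plate(long, map, temperature = temperature)
}

#' Traces from in-memory plate tables
#'
#' The in-memory counterpart of [read_plate()]: turns a long-form plate
#' data frame (`time_s`, `well`, `signal`) and a well-map data frame into a
#' named list of [aggregation_trace()]s.
#'
#' @param plate Long-form plate data frame.
#' @param map Well-map data frame (`well`, `substrate`, `chaperone`,
#'   `ratio`, `replicate`).
#' @param temperature Optional temperature annotation, degrees C.
#' @return Named list of `aggregation_trace` objects.
#' @export
traces_from_plate <- function(plate, map, temperature = NA_real_) {
  need <- c("well", "substrate", "chaperone", "ratio", "replicate")
  miss <- setdiff(need, names(map))
  if (length(miss)) {
    stop("well map is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unmapped <- setdiff(unique(plate$well), map$well)
  if (length(unmapped)) {
    warning("dropping unmapped wells: ", paste(unmapped, collapse = ", "))
  }
  wells <- intersect(map$well, unique(plate$well))
  traces <- lapply(wells, function(w) {
    d <- plate[plate$well == w, ]
    d <- d[order(d$time_s), ]
    m <- map[map$well == w, ][1L, ]
    ch <- m$chaperone
    if (is.null(ch) || is.na(ch) || !nzchar(ch)) ch <- NA_character_
    aggregation_trace(d$time_s, d$signal, substrate = m$substrate,
                      chaperone = ch, ratio = m$ratio,
                      replicate = as.integer(m$replicate),
                      temperature = temperature)
  })
  names(traces) <- wells
  traces
}

# trapezoidal AUC of a trace restricted to [t0, t1] (interpolated endpoints)
.trace_auc <- function(trace, t0, t1) {
  tt <- trace$times
  if (t0 < min(tt) - 1e-9 || t1 > max(tt) + 1e-9) {
    stop("integration window outside trace time range", call. = FALSE)
  }
  inside <- tt > t0 & tt < t1
  grid <- c(t0, tt[inside], t1)
  vals <- stats::approx(tt, trace$signal, xout = grid, rule = 2)$y
  pracma::trapz(grid, vals)
}

#' Aggregation mass from turbidity kinetics
#'
#' The activity statistic for amorphous aggregation: per-replicate
#' trapezoidal area under the (baseline-corrected) turbidity curve over the
#' time window common to sample and control, normalized to the mean
#' substrate-alone control area and expressed in percent. 100% means no
#' suppression of substrate aggregation; 0% means complete suppression.
#'
#' Areas are integrated on the actual timestamps (plate cycles are nominally
#' 90 s but may have gaps), each replicate separately; the replicate areas
#' are then averaged and their dispersion propagated:
#' `sd_pct = 100 * sd(AUC) / mean(control AUC)`.
#'
#' @param traces List of replicate [aggregation_trace()] objects for one
#'   variant/ratio condition.
#' @param control List of replicate substrate-alone `aggregation_trace`s.
#' @param baseline_n Initial points averaged for baseline correction
#'   (applied to both sample and control); `0` disables correction.
#' @param window Optional `c(t0, t1)` integration window (seconds);
#'   defaults to the intersection of all trace time ranges.
#' @return A one-row data frame: `variant_id`, `ratio`, `mass_pct`,
#'   `sd_pct`, `n_replicates`.
#' @examples
#' tt <- seq(0, 900, by = 90)
#' ctl <- list(aggregation_trace(tt, pmin(tt / 450, 1), substrate = "CS"))
#' half <- list(aggregation_trace(tt, pmin(tt / 450, 1) / 2, substrate = "CS",
#'                                chaperone = "v1", ratio = "1:1"))
#' aggregation_mass(half, ctl, baseline_n = 0)$mass_pct  # 50
#' @export
aggregation_mass <- function(traces, control, baseline_n = 3L,
                             window = NULL) {
  if (inherits(traces, "aggregation_trace")) traces <- list(traces)
  if (inherits(control, "aggregation_trace")) control <- list(control)
  stopifnot(length(traces) >= 1L, length(control) >= 1L)
  all_tr <- c(traces, control)
  subs <- unique(vapply(all_tr, `[[`, character(1), "substrate"))
  if (length(subs) > 1L) {
    stop("traces and control must share a substrate (got: ",
         paste(subs, collapse = ", "), ")", call. = FALSE)
  }
  if (baseline_n > 0L) {
    traces <- lapply(traces, baseline_correct, n_initial = baseline_n)
    control <- lapply(control, baseline_correct, n_initial = baseline_n)
  }
  t0 <- max(vapply(all_tr, function(x) min(x$times), numeric(1)))
  t1 <- min(vapply(all_tr, function(x) max(x$times), numeric(1)))
  if (!is.null(window)) {
    t0 <- max(t0, window[1]); t1 <- min(t1, window[2])
  }
  if (t1 <= t0) stop("no overlap in time windows", call. = FALSE)
  auc <- vapply(traces, .trace_auc, numeric(1), t0 = t0, t1 = t1)
  auc_ctl <- vapply(control, .trace_auc, numeric(1), t0 = t0, t1 = t1)
  m_ctl <- mean(auc_ctl)
  if (abs(m_ctl) < .Machine$double.eps * max(1, abs(t1 - t0))) {
    stop("zero control AUC: normalization undefined", call. = FALSE)
  }
  data.frame(
    variant_id = traces[[1L]]$chaperone,
    ratio = traces[[1L]]$ratio,
    mass_pct = 100 * mean(auc) / m_ctl,
    sd_pct = if (length(auc) > 1L) 100 * stats::sd(auc) / m_ctl else NA_real_,
    n_replicates = length(auc),
    stringsAsFactors = FALSE
  )
}

#' Aggregation mass for every condition on a plate
#'
#' Groups mapped plate traces by (chaperone, ratio) and applies
#' [aggregation_mass()] against the substrate-alone control wells.
#'
#' @param traces List of [aggregation_trace()]s (e.g. from [read_plate()]).
#' @param baseline_n,window Passed to [aggregation_mass()].
#' @return Data frame with one row per (variant, ratio) condition, control
#'   included (its `mass_pct` is 100 by construction).
#' @export
aggregation_mass_panel <- function(traces, baseline_n = 3L, window = NULL) {
  ch <- vapply(traces, function(x)
    if (is.na(x$chaperone)) "" else x$chaperone, character(1))
  rt <- vapply(traces, function(x) as.character(x$ratio), character(1))
  control <- traces[ch == ""]
  if (!length(control)) stop("no substrate-alone control wells", call. = FALSE)
  keys <- unique(paste(ch, rt, sep = "\r"))
  out <- lapply(keys, function(k) {
    grp <- traces[paste(ch, rt, sep = "\r") == k]
    res <- aggregation_mass(grp, control, baseline_n = baseline_n,
                            window = window)
    if (!nzchar(strsplit(k, "\r")[[1L]][1L])) res$variant_id <- NA_character_
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
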