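#' Size-exclusion column calibration
#'
#' Standard SEC calibration: least-squares line of `log10(MW)` against
#' elution volume over a set of molecular-weight standards. The slope must
#' be negative (larger species elute earlier).
#'
#' @param standards Data frame with columns `elution_volume` (mL) and
#'   `molecular_weight` (Da), at least 3 rows.
#' @return Object of class `sec_calibration` with `intercept`, `slope`
#'   (log10 Da per mL) and the standards.
#' @export
sec_calibration <- function(standards) {
  stopifnot(is.data.frame(standards),
            all(c("elution_volume", "molecular_weight") %in% names(standards)))
  if (nrow(standards) < 3L) stop("need >= 3 standards", call. = FALSE)
  fit <- stats::lm(log10(molecular_weight) ~ elution_volume, data = standards)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0) {
    stop("calibration slope must be negative (log10 MW decreasing in volume)",
         call. = FALSE)
  }
  structure(list(intercept = unname(stats::coef(fit)[1L]), slope = slope,
                 standards = standards),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf("SEC calibration: log10(MW) = %.4f %+.4f * volume (n = %d standards)\n",
              x$intercept, x$slope, nrow(x$standards)))
  invisible(x)
}

# volume (mL) -> molecular weight (Da)
.cal_mw <- function(cal, volume) 10^(cal$intercept + cal$slope * volume)

#' Oligomer subunit count from an SEC peak
#'
#' Estimates the number of subunits in an oligomer from a size-exclusion
#' chromatogram: the peak position gives the point estimate, and the full
#' width at half maximum (FWHM) gives the range, both converted to
#' molecular weight through a log-linear column calibration and divided by
#' the monomer molecular weight. Half-height crossings are located by
#' linear interpolation. Because the calibration slope is negative, the
#' *high-volume* FWHM edge maps to the *low* subunit count.
#'
#' @param chrom Data frame with columns `elution_volume` (mL, strictly
#'   increasing, >= 10 points) and `a280`.
#' @param cal A [sec_calibration()].
#' @param monomer_mw Monomer molecular weight, Da.
#' @param peak_window Optional `c(lo, hi)` volume range containing the peak.
#' @return Object of class `oligomer_estimate`: `peak_volume`,
#'   `fwhm_volumes` (lo, hi), `subunits_peak`, `subunits_range` (lo, hi,
#'   rounded), `mw_peak`, `mw_ratio` (unrounded MW/monomer ratio),
#'   `monomer_mw`.
#' @export
estimate_subunits <- function(chrom, cal, monomer_mw, peak_window = NULL) {
  stopifnot(is.data.frame(chrom),
            all(c("elution_volume", "a280") %in% names(chrom)),
            inherits(cal, "sec_calibration"), monomer_mw > 0)
  v <- chrom$elution_volume; y <- chrom$a280
  if (length(v) < 10L) stop("need >= 10 chromatogram points", call. = FALSE)
  if (any(diff(v) <= 0)) stop("volumes must be strictly increasing",
                              call. = FALSE)
  keep <- rep(TRUE, length(v))
  if (!is.null(peak_window)) keep <- v >= peak_window[1] & v <= peak_window[2]
  if (!any(keep)) stop("no points inside peak_window", call. = FALSE)
  iw <- which(keep)
  ipk <- iw[which.max(y[iw])]
  if (y[ipk] <= 0) stop("no peak in window", call. = FALSE)
  half <- y[ipk] / 2

  cross <- function(idx_seq) {  # first half-height crossing along idx_seq
    for (j in seq_len(length(idx_seq) - 1L)) {
      i1 <- idx_seq[j]; i2 <- idx_seq[j + 1L]
      if ((y[i1] - half) * (y[i2] - half) <= 0 && y[i1] != y[i2]) {
        return(v[i1] + (half - y[i1]) * (v[i2] - v[i1]) / (y[i2] - y[i1]))
      }
    }
    NA_real_
  }
  v_lo <- cross(seq(ipk, 1L))
  v_hi <- cross(seq(ipk, length(v)))
  if (is.na(v_lo) || is.na(v_hi)) {
    stop("FWHM crossing outside chromatogram", call. = FALSE)
  }
  mw_peak <- .cal_mw(cal, v[ipk])
  mw_lo_edge <- .cal_mw(cal, v_hi)  # high volume -> small MW
  mw_hi_edge <- .cal_mw(cal, v_lo)
  est <- structure(
    list(peak_volume = v[ipk], fwhm_volumes = c(v_lo, v_hi),
         subunits_peak = max(1L, round(mw_peak / monomer_mw)),
         subunits_range = c(max(1L, round(mw_lo_edge / monomer_mw)),
                            max(1L, round(mw_hi_edge / monomer_mw))),
         mw_peak = mw_peak, mw_ratio = mw_peak / monomer_mw,
         monomer_mw = monomer_mw),
    class = "oligomer_estimate")
  est
}

#' @export
print.oligomer_estimate <- function(x, ...) {
  cat(sprintf(
    "SEC oligomer estimate: %d subunits (FWHM range %d-%d) | peak %.2f mL, MW %.3g Da\n",
    x$subunits_peak, x$subunits_range[1L], x$subunits_range[2L],
    x$peak_volume, x$mw_peak))
  invisible(x)
}

#' Convert raw ellipticity to mean residue ellipticity
#'
#' Converts a circular-dichroism spectrum from machine units (mdeg) to mean
#' residue ellipticity:
#' `MRE = theta_mdeg / (10 * path * conc * (n_residues - 1))`
#' in deg cm^2 dmol^-1, with concentration in mol/L and path length in cm.
#' The divisor counts peptide bonds (`n_residues - 1`); set
#' `per_residue = TRUE` to divide by `n_residues` instead, as some
#' conventions do.
#'
#' @param spectrum Data frame with columns `wavelength` (nm) and
#'   `ellipticity_mdeg` (blank-subtracted, replicate-averaged).
#' @param conc Protein concentration, mol/L (> 0).
#' @param path Cuvette path length, cm (> 0).
#' @param n_residues Number of residues (>= 2).
#' @param per_residue Divide by `n_residues` instead of `n_residues - 1`.
#' @return The spectrum data frame with an added `mre` column.
#' @export
cd_to_mre <- function(spectrum, conc, path, n_residues, per_residue = FALSE) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "ellipticity_mdeg") %in% names(spectrum)))
  if (conc <= 0 || path <= 0) stop("conc and path must be > 0", call. = FALSE)
  if (n_residues < 2L) stop("n_residues must be >= 2", call. = FALSE)
  nb <- if (per_residue) n_residues else n_residues - 1L
  spectrum$mre <- spectrum$ellipticity_mdeg / (10 * path * conc * nb)
  spectrum
}

#' Fluorescence emission maximum
#'
#' Wavelength of the maximum of a (background-subtracted) fluorescence
#' emission spectrum after moving-average smoothing, reported to 1 nm.
#' Used e.g. to detect the red shift of a tryptophan reporter when its
#' microenvironment becomes more polar.
#'
#' @param spectrum Data frame with columns `wavelength` (nm) and
#'   `intensity`, >= 20 points.
#' @param smooth_window Moving-average window (odd count of points;
#'   default 5; 1 disables smoothing).
#' @return Wavelength of maximum intensity (nm, rounded to 1 nm).
#' @export
emission_max <- function(spectrum, smooth_window = 5L) {
  stopifnot(is.data.frame(spectrum),
            all(c("wavelength", "intensity") %in% names(spectrum)))
  y <- spectrum$intensity
  if (length(y) < 20L) stop("need >= 20 spectrum points", call. = FALSE)
  if (diff(range(y)) == 0) stop("flat spectrum: no unique maximum",
                                call. = FALSE)
  k <- as.integer(smooth_window)
  if (k > 1L) {
    if (k %% 2L == 0L) k <- k + 1L
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
  }
  round(spectrum$wavelength[which.max(y)])
}
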