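# Dual-wavelength oxygenation read-outs and channel naming conventions.

#' Relative oxygenation ratio series
#'
#' Element-wise ratio of the second wavelength's signal intensity to the
#' first's.  With one wavelength weighted towards deoxygenated and the
#' other towards oxygenated haemoglobin, the ratio tracks relative changes
#' in oxygen saturation (no absolute saturation is estimated).  Samples
#' where the denominator falls below \code{floor_frac} of its series
#' maximum are masked as \code{NA} to avoid noise blow-up.
#'
#' @param s1,s2 Equal-length numeric amplitude series (wavelengths 1, 2).
#' @param floor_frac Denominator floor as a fraction of \code{max(s1)}.
#' @return Numeric ratio series with \code{NA} where masked.
#' @examples
#' ratio_series(c(1, 2, 4), c(2, 4, 4))
#' @export
ratio_series <- function(s1, s2, floor_frac = 0.05) {
  if (length(s1) != length(s2))
    stop("series lengths differ", call. = FALSE)
  floor_val <- floor_frac * max(s1, na.rm = TRUE)
  out <- s2 / s1
  out[!is.finite(out) | s1 < floor_val] <- NA_real_
  out
}

#' Oxygen extraction rate series
#'
#' \eqn{OER = (O_{ca} - O_{cv}) / O_{ca}} with \eqn{O_{ca}} and
#' \eqn{O_{cv}} the oxygenation levels in the central artery and vein:
#' the fraction of delivered oxygen taken up by the tissue.  Zero when
#' artery and vein are equally oxygenated; non-positive artery values are
#' masked.
#'
#' @param o_artery,o_vein Equal-length oxygenation series.
#' @return Numeric OER series with \code{NA} where masked.
#' @examples
#' oer_series(c(1, 1), c(0.5, 1))  # 0.5, 0
#' @export
oer_series <- function(o_artery, o_vein) {
  if (length(o_artery) != length(o_vein))
    stop("series lengths differ", call. = FALSE)
  out <- (o_artery - o_vein) / o_artery
  out[!is.finite(out) | o_artery <= 0] <- NA_real_
  out
}

#' Name the four demultiplexed wavelength channels
#'
#' Pure relabelling following the four-diode convention: wavelength 1
#' (445 nm) is weighted towards deoxygenated haemoglobin, wavelength 2
#' (465 nm) towards oxygenated haemoglobin, wavelength 3 (638 nm) matches
#' the Evans Blue absorption peak and wavelength 4 (808 nm) the ICG
#' plasma peak.  No spectral unmixing is performed.
#'
#' @param ascans List of exactly four per-wavelength objects (A-scans,
#'   images or series), ordered by wavelength id.
#' @return The same list named \code{c("Hb", "HbO2", "EvansBlue", "ICG")}.
#' @export
assign_channels <- function(ascans) {
  if (length(ascans) != 4L)
    stop("exactly four wavelength channels required", call. = FALSE)
  names(ascans) <- c("Hb", "HbO2", "EvansBlue", "ICG")
  ascans
}
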