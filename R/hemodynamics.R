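# Optical density and modified Beer-Lambert conversion.

#' Default extinction coefficients (cm^-1 mM^-1)
#'
#' Standard compiled molar extinction coefficients of oxy- and
#' deoxyhemoglobin at the two default wavelengths, in the units and convention
#' of the Homer toolchain. Overridable via [mbll_params()].
#'
#' @return data frame with `wavelength`, `eps_hbo`, `eps_hbr`.
#' @export
default_extinction <- function() {
  data.frame(wavelength = c(760, 850),
             eps_hbo = c(0.586, 1.058),
             eps_hbr = c(1.548, 0.691))
}

#' Convert raw intensity to optical density changes
#'
#' `od(t) = -ln(I(t) / mean_t(I))` per channel and wavelength: the natural log
#' of the ratio to the column's temporal mean (Homer convention), so each OD
#' column has analytic mean-of-exponential reference zero.
#'
#' @param intensity array `[time, channel, 2]` of strictly positive intensity,
#'   or an `fnirs_recording`.
#' @return array of the same shape with dimensionless OD changes.
#' @export
intensity_to_od <- function(intensity) {
  if (inherits(intensity, "fnirs_recording")) intensity <- intensity$intensity
  if (any(intensity <= 0)) {
    bad <- which(intensity <= 0, arr.ind = TRUE)[1, ]
    stopf("nonpositive intensity at sample %d, channel %d, wavelength %d",
          bad[1], bad[2], bad[3])
  }
  d <- dim(intensity)
  m <- colMeans(matrix(intensity, d[1], d[2] * d[3]))
  od <- -log(sweep(matrix(intensity, d[1], d[2] * d[3]), 2, m, `/`))
  array(od, d)
}

#' Age- and wavelength-dependent differential pathlength factor
#'
#' When `age` is `NULL` the conventional adult default of 6 is returned.
#' Otherwise the general DPF(lambda, age) regression for adult/infant heads is
#' evaluated: `223.3 + 0.05624 * age^0.8493 - 5.723e-7 * lambda^3 +
#' 0.001245 * lambda^2 - 0.9025 * lambda` (lambda in nm, age in years), which
#' increases monotonically with age at fixed wavelength.
#'
#' @param age age in years in (0, 120), or `NULL`.
#' @param wavelength wavelength in nm.
#' @return dimensionless DPF.
#' @export
dpf_for_age <- function(age = NULL, wavelength = 760) {
  if (is.null(age)) return(rep(6, length(wavelength)))
  if (!is.numeric(age) || any(age <= 0 | age >= 120)) stopf("age must be in (0, 120) years")
  223.3 + 0.05624 * age^0.8493 - 5.723e-7 * wavelength^3 +
    0.001245 * wavelength^2 - 0.9025 * wavelength
}

#' Parameters for the modified Beer-Lambert inversion
#'
#' @param wavelengths two wavelengths (nm).
#' @param separation_mm source-detector separation per channel (mm); recycled.
#' @param dpf per-wavelength differential pathlength factor, a scalar, length-2
#'   vector, or the string `"age"` to use [dpf_for_age()].
#' @param age subject age (years) used when `dpf = "age"`.
#' @param extinction extinction table (`wavelength`, `eps_hbo`, `eps_hbr`) in
#'   cm^-1 mM^-1; rows must cover both wavelengths.
#' @return list of class `mbll_params`.
#' @export
mbll_params <- function(wavelengths = c(760, 850), separation_mm = 30,
                        dpf = 6, age = NULL, extinction = default_extinction()) {
  if (identical(dpf, "age")) dpf <- dpf_for_age(age, wavelengths)
  dpf <- rep_len(dpf, 2)
  if (any(dpf <= 0)) stopf("dpf must be positive")
  idx <- match(wavelengths, extinction$wavelength)
  if (any(is.na(idx))) {
    stopf("extinction table lacks wavelength(s): %s",
          paste(wavelengths[is.na(idx)], collapse = ", "))
  }
  E <- cbind(extinction$eps_hbo[idx], extinction$eps_hbr[idx])  # 2x2, rows = wavelengths
  if (abs(det(E)) < 1e-12) stopf("singular extinction matrix")
  structure(list(wavelengths = wavelengths, separation_mm = separation_mm,
                 dpf = dpf, E = E), class = "mbll_params")
}

#' Modified Beer-Lambert law: OD changes to hemoglobin concentration changes
#'
#' Solves, per channel and time point, the 2x2 system
#' `dOD_lambda = (eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF(lambda)` for
#' (dHbO, dHbR), with the separation `d` in cm. Output in micromolar.
#'
#' @param od array `[time, channel, 2]` of OD changes.
#' @param params an [mbll_params()] object.
#' @return list with `hbo` and `hbr`, each `[time x channel]` matrices in uM.
#' @export
mbll <- function(od, params = mbll_params()) {
  stopifnot(inherits(params, "mbll_params"))
  d <- dim(od)
  if (length(d) != 3 || d[3] != 2) stopf("od must be [time x channel x 2]")
  sep_cm <- rep_len(params$separation_mm, d[2]) / 10
  hbo <- matrix(0, d[1], d[2])
  hbr <- matrix(0, d[1], d[2])
  Einv <- solve(params$E)
  for (ch in seq_len(d[2])) {
    # scale each wavelength's OD by its effective pathlength, then invert
    rhs <- rbind(od[, ch, 1] / (sep_cm[ch] * params$dpf[1]),
                 od[, ch, 2] / (sep_cm[ch] * params$dpf[2]))
    hb_mM <- Einv %*% rhs
    hbo[, ch] <- hb_mM[1, ] * 1000
    hbr[, ch] <- hb_mM[2, ] * 1000
  }
  list(hbo = hbo, hbr = hbr)
}

#' Forward modified Beer-Lambert model (uM concentration changes to OD)
#'
#' The inverse of [mbll()]; used by the synthetic generator and round-trip
#' tests.
#'
#' @param hbo,hbr `[time x channel]` matrices in uM.
#' @param params an [mbll_params()] object.
#' @return OD array `[time, channel, 2]`.
#' @export
hb_to_od <- function(hbo, hbr, params = mbll_params()) {
  stopifnot(inherits(params, "mbll_params"))
  nch <- ncol(hbo)
  sep_cm <- rep_len(params$separation_mm, nch) / 10
  od <- array(0, c(nrow(hbo), nch, 2))
  for (ch in seq_len(nch)) {
    hb_mM <- rbind(hbo[, ch], hbr[, ch]) / 1000
    dod <- params$E %*% hb_mM
    od[, ch, 1] <- dod[1, ] * sep_cm[ch] * params$dpf[1]
    od[, ch, 2] <- dod[2, ] * sep_cm[ch] * params$dpf[2]
  }
  od
}

#' Oxyhemoglobin time courses of a recording
#'
#' Convenience composition `intensity -> OD -> MBLL` returning the `[O2Hb]`
#' matrix used by the spectral-fitting and scalogram stages. DPF is
#' age-dependent when the recording carries an age and `dpf = "age"`.
#'
#' @param rec an `fnirs_recording`.
#' @param dpf DPF specification as in [mbll_params()].
#' @param extinction extinction table override.
#' @return list with `hbo`, `hbr` (`[time x channel]`, uM) and the `params` used.
#' @export
recording_hb <- function(rec, dpf = 6, extinction = default_extinction()) {
  od <- intensity_to_od(rec$intensity)
  params <- mbll_params(rec$wavelengths, rec$montage$separation_mm,
                        dpf = dpf, age = rec$age, extinction = extinction)
  c(mbll(od, params), list(params = params))
}
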