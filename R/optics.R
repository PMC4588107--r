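#' Optical parameters for the modified Beer-Lambert law
#'
#' Extinction coefficients, source-detector distance and differential
#' pathlength factor (DPF) used to convert optical-density changes to
#' chromophore concentration changes. The default extinction matrix is the
#' widely used Gratzer/Cope tabulation of hemoglobin base-10 extinction
#' coefficients at 690 and 830 nm in 1/(mM cm); at 690 nm deoxygenated
#' hemoglobin dominates, at 830 nm oxygenated hemoglobin does, which is what
#' makes the two-wavelength inversion well conditioned. The DPF default of 6
#' for both wavelengths is the common adult-forehead convention. All values
#' are overridable; because every downstream feature is scale-invariant in
#' concentration units, the DPF convention does not affect classification.
#'
#' @param extinction 2x2 matrix, rows = wavelengths, columns = c("HbO","Hb"),
#'   units 1/(mM cm).
#' @param distance_cm source-detector distance.
#' @param dpf length-2 differential pathlength factor (per wavelength).
#' @param I0 reference intensity (scalar, or per channel/wavelength) used by
#'   the forward model.
#' @param wavelengths length-2 wavelengths in nm (bookkeeping only).
#' @return object of class `nirs_optics`.
#' @export
optics_parameters <- function(extinction = default_extinction(),
                              distance_cm = 3, dpf = c(6, 6),
                              I0 = 1, wavelengths = c(690, 830)) {
  extinction <- as.matrix(extinction)
  if (!identical(dim(extinction), c(2L, 2L)))
    stop2("extinction must be a 2x2 (wavelength x chromophore) matrix")
  colnames(extinction) <- c("HbO", "Hb")
  if (abs(det(extinction)) < 1e-12)
    stop2("extinction matrix is singular; wavelength pair cannot separate HbO/Hb")
  if (distance_cm <= 0 || any(dpf <= 0)) stop2("distance and DPF must be positive")
  if (length(dpf) == 1) dpf <- rep(dpf, 2)
  structure(list(extinction = extinction, distance_cm = distance_cm,
                 dpf = dpf, I0 = I0, wavelengths = wavelengths),
            class = "nirs_optics")
}

default_extinction <- function() {
  matrix(c(0.276, 2.052,
           0.974, 0.693), nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("HbO", "Hb")))
}

#' Optical density change from intensity
#'
#' `OD = -log10(I / I0)`, applied elementwise. Errors name the first
#' offending channel/sample if any intensity is non-positive.
#'
#' @param I intensity vector, matrix (samples x channels) or array.
#' @param I0 reference intensity (scalar or conformable).
#' @return optical-density object of the same shape.
#' @export
intensity_to_od <- function(I, I0) {
  bad <- which(!(I > 0), arr.ind = TRUE)
  if (length(bad)) {
    loc <- if (is.matrix(bad)) paste0("sample ", bad[1, 1], ", channel ", bad[1, 2])
           else paste0("index ", bad[1])
    stop2("non-positive intensity at ", loc)
  }
  if (any(!(I0 > 0))) stop2("non-positive reference intensity I0")
  -log10(I / I0)
}

#' Concentration changes via the modified Beer-Lambert law
#'
#' Inverts `OD_w = (eps_HbO,w dHbO + eps_Hb,w dHb) d DPF_w` for the two
#' wavelengths jointly: each OD series is first normalised by its effective
#' pathlength `d * DPF_w`, then the 2x2 extinction system is solved per
#' sample. Outputs are in micromolar; total hemoglobin is set to
#' `dHbO + dHb` exactly.
#'
#' @param od1,od2 optical-density series (vector or samples x channels
#'   matrix) at the first and second wavelength of `optics`.
#' @param optics an [optics_parameters()].
#' @return list with `HbO`, `Hb`, `tHb` (uM), same shape as the inputs.
#' @examples
#' op <- optics_parameters()
#' mbll(0.01, 0.01, op)
#' @export
mbll <- function(od1, od2, optics = optics_parameters()) {
  if (length(od1) != length(od2)) stop2("OD series lengths differ")
  einv <- solve(optics$extinction)
  a1 <- as.numeric(od1) / (optics$distance_cm * optics$dpf[1])
  a2 <- as.numeric(od2) / (optics$distance_cm * optics$dpf[2])
  hbo <- (einv[1, 1] * a1 + einv[1, 2] * a2) * 1000
  hb <- (einv[2, 1] * a1 + einv[2, 2] * a2) * 1000
  shape <- function(v) { attributes(v) <- attributes(od1); v }
  list(HbO = shape(hbo), Hb = shape(hb), tHb = shape(hbo + hb))
}

#' Convert a raw intensity recording to concentration changes
#'
#' Applies the pipeline's reference convention and the modified Beer-Lambert
#' law to each block of a raw recording: the per-channel, per-wavelength
#' reference intensity I0 is the mean intensity over the block's opening
#' baseline, so concentration changes are relative to that block's rest
#' state.
#'
#' @param raw a `nirs_raw_set` (from [hemodynamics_to_intensity()] or
#'   [read_recording()]).
#' @param optics an [optics_parameters()].
#' @param baseline_s length of the baseline window used for I0.
#' @return a `nirs_hemo_set`.
#' @export
raw_to_hemo <- function(raw, optics = optics_parameters(), baseline_s = 30) {
  blocks <- lapply(raw, function(bl) {
    n <- dim(bl$intensity)[1]; n_ch <- dim(bl$intensity)[2]
    nb <- max(2L, min(n, round(baseline_s * bl$fs)))
    conc <- array(0, dim = c(n, n_ch, 3),
                  dimnames = list(NULL, dimnames(bl$intensity)[[2]],
                                  c("HbO", "Hb", "tHb")))
    for (ch in seq_len(n_ch)) {
      i0 <- colMeans(bl$intensity[seq_len(nb), ch, , drop = FALSE])
      od1 <- intensity_to_od(bl$intensity[, ch, 1], i0[1])
      od2 <- intensity_to_od(bl$intensity[, ch, 2], i0[2])
      cc <- mbll(od1, od2, optics)
      conc[, ch, "HbO"] <- cc$HbO
      conc[, ch, "Hb"] <- cc$Hb
      conc[, ch, "tHb"] <- cc$tHb
    }
    list(session = bl$session, block = bl$block, fs = bl$fs, conc = conc,
         events = bl$events)
  })
  structure(blocks, class = "nirs_hemo_set", fs = attr(raw, "fs"))
}
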