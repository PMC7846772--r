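#' Construct a chromophore spectrum object
#'
#' @param wavelengths wavelengths (nm), strictly increasing.
#' @param values non-negative absorption coefficients (1/cm) or normalized
#'   absorbance.
#' @param name label.
#' @return object of class `paus_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `value`).
#' @export
paus_spectrum <- function(wavelengths, values, name = "custom") {
  abort_if(length(wavelengths) != length(values), "length mismatch")
  abort_if(any(diff(wavelengths) <= 0), "wavelengths must be strictly increasing")
  abort_if(any(values < 0), "spectrum values must be non-negative")
  out <- data.frame(wavelength_nm = wavelengths, value = values)
  attr(out, "name") <- name
  class(out) <- c("paus_spectrum", "data.frame")
  out
}

#' Built-in chromophore spectra
#'
#' Synthetic spectra emulating the absorbers used in fast-sweep phantom and
#' in vivo work:
#' \describe{
#'   \item{gnr}{gold-nanorod-like plasmon resonance: Lorentzian peaked at
#'     776 nm whose full width at 80% of maximum is 68 nm.}
#'   \item{ink}{ink-like, monotone and gently decreasing with wavelength.}
#'   \item{background}{Prussian-blue-like broad band peaked near 700 nm,
#'     decaying toward the NIR (synthetic surrogate for the measured table).}
#'   \item{flat}{constant ("needle-like" broadband absorber).}
#'   \item{water}{negligible NIR absorption (all zero) — a de-ionized
#'     water tube is invisible in PA at these scales.}
#' }
#'
#' @param kind one of `"gnr"`, `"ink"`, `"background"`, `"flat"`, `"water"`.
#' @param wavelengths evaluation wavelengths (nm), within 650-950 nm.
#' @param peak_value scale of the returned spectrum (value at its maximum).
#' @return a [paus_spectrum()].
#' @examples
#' s <- chromophore_spectrum("gnr", seq(700, 900, by = 1))
#' s$wavelength_nm[which.max(s$value)] # 776
#' @export
chromophore_spectrum <- function(kind, wavelengths, peak_value = 1) {
  abort_if(any(wavelengths < 650 | wavelengths > 950),
           "wavelengths must lie within 650-950 nm")
  kind <- match.arg(kind, c("gnr", "ink", "background", "flat", "water"))
  if (kind == "water") {
    return(paus_spectrum(wavelengths, rep(0, length(wavelengths)),
                         name = "water"))
  }
  v <- switch(kind,
    # width at 80% of max of 1/(1+u^2) is reached at u = +/- 0.5, so a
    # Lorentzian scale gamma equals the full 80%-of-max width
    gnr = 1 / (1 + ((wavelengths - 776) / 68)^2),
    # gentle exponential decline, ~18% drop over 700 -> 900 nm
    ink = exp(-(wavelengths - 700) / 1000),
    background = exp(-0.5 * ((wavelengths - 690) / 80)^2),
    flat = rep(1, length(wavelengths))
  )
  paus_spectrum(wavelengths, peak_value * v / max(v), name = kind)
}

#' Area-normalize a spectrum
#'
#' Divides by the trapezoid-rule integral over wavelength so that the
#' normalized spectrum integrates to 1 (per nm).
#'
#' @param spectrum a [paus_spectrum()] or a numeric vector (then
#'   `wavelengths` must be given).
#' @param wavelengths wavelengths (nm) when `spectrum` is a bare vector.
#' @return same shape as the input, area-normalized.
#' @export
normalize_spectrum <- function(spectrum, wavelengths = NULL) {
  if (inherits(spectrum, "paus_spectrum")) {
    a <- trapz(spectrum$wavelength_nm, spectrum$value)
    abort_if(a <= 0, "cannot area-normalize an all-zero spectrum")
    paus_spectrum(spectrum$wavelength_nm, spectrum$value / a,
                  name = attr(spectrum, "name"))
  } else {
    abort_if(is.null(wavelengths), "wavelengths required for a bare vector")
    a <- trapz(wavelengths, spectrum)
    abort_if(a <= 0, "cannot area-normalize an all-zero spectrum")
    spectrum / a
  }
}

trapz <- function(x, y) sum(diff(x) * (head_(y) + tail_(y)) / 2)
head_ <- function(v) v[-length(v)]
tail_ <- function(v) v[-1]

#' Evaluate (resample) a spectrum at given wavelengths
#'
#' Linear interpolation; requested wavelengths must be covered by the
#' spectrum's support.
#'
#' @param spectrum a [paus_spectrum()].
#' @param wavelengths target wavelengths (nm).
#' @return numeric vector of values at `wavelengths`.
#' @export
resample_spectrum <- function(spectrum, wavelengths) {
  rng <- range(spectrum$wavelength_nm)
  abort_if(any(wavelengths < rng[1] - 1e-9 | wavelengths > rng[2] + 1e-9),
           "reference spectrum does not cover the requested wavelengths")
  approx(spectrum$wavelength_nm, spectrum$value, xout = wavelengths)$y
}

#' Read / write a spectrum as CSV
#'
#' Plain-text exchange format: header `wavelength_nm,value`, strictly
#' increasing wavelengths, non-negative values. Round-trips losslessly.
#'
#' @param path file path.
#' @return [read_spectrum_csv()] returns a [paus_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  raw <- read.csv(path, strip.white = TRUE)
  abort_if(!all(c("wavelength_nm", "value") %in% names(raw)),
           "CSV must have columns wavelength_nm,value")
  w <- suppressWarnings(as.numeric(raw$wavelength_nm))
  v <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.finite(w) | !is.finite(v))
  abort_if(length(bad) > 0,
           sprintf("malformed spectrum row at line %d of %s", bad[1] + 1, path))
  nonmono <- which(diff(w) <= 0)
  abort_if(length(nonmono) > 0,
           sprintf("wavelengths not strictly increasing at line %d of %s",
                   nonmono[1] + 2, path))
  paus_spectrum(w, v, name = sub("\\.csv$", "", basename(path)))
}

#' @param spectrum a [paus_spectrum()] to write.
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spectrum, path) {
  write.csv(data.frame(wavelength_nm = spectrum$wavelength_nm,
                       value = spectrum$value),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
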