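# Spectrophotometric hemoglobin quantification: free-hemoglobin percent
# from turbidity-corrected 540 nm absorbance, and hemoglobin-species
# unmixing (oxyHb / metHb / hemichrome) by nonnegative least squares on
# molar extinction coefficients.

#' Default molar extinction matrix for hemoglobin species
#'
#' Millimolar extinction coefficients (per heme, mM^-1 cm^-1) of
#' oxyhemoglobin, methemoglobin (Fe(III)) and hemichrome at 540, 560,
#' 577 and 630 nm. These are literature-style defaults shipped for
#' convenience; the coefficient table is a configuration input and any
#' laboratory table can be supplied in its place.
#'
#' @return Numeric matrix, rows named by wavelength ("540", "560",
#'   "577", "630"), columns `oxyHb`, `metHb`, `hemichrome`.
#' @export
default_extinction_matrix <- function() {
  m <- matrix(c(14.27, 5.8, 7.8,
                8.80, 4.4, 8.4,
                15.37, 4.1, 7.4,
                0.10, 3.7, 2.0),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("540", "560", "577", "630"),
                              c("oxyHb", "metHb", "hemichrome")))
  m
}

#' Simulate an absorbance spectrum of a hemoglobin mixture
#'
#' Optical density at each wavelength of the extinction table is the
#' Beer-Lambert sum over species plus a flat turbidity offset and
#' optional Gaussian noise; 700 nm carries turbidity (and noise) only
#' and serves as the baseline for downstream corrections.
#'
#' @param species_fractions Named or ordered fractions of
#'   (oxyHb, metHb, hemichrome); nonnegative, summing to 1.
#' @param total_hb Total heme concentration (mM) in the cuvette.
#' @param extinction_matrix Extinction table
#'   (see [default_extinction_matrix()]).
#' @param pathlength Cuvette path length (cm).
#' @param turbidity_offset Flat additive OD applied at all wavelengths
#'   (default 0.1).
#' @param noise_sd Additive OD noise SD.
#' @param dilution_factor Fold-dilution recorded with the spectrum.
#' @param role `"supernatant"` or `"whole_lysate"`.
#' @param seed Optional RNG seed.
#' @return Object of class `absorbance_spectrum`: list with `od` (named
#'   by wavelength, includes 700 nm), `dilution_factor`, `role`.
#' @export
simulate_absorbance <- function(species_fractions,
                                total_hb = 1,
                                extinction_matrix =
                                  default_extinction_matrix(),
                                pathlength = 1,
                                turbidity_offset = 0.1,
                                noise_sd = 0,
                                dilution_factor = 1,
                                role = "supernatant",
                                seed = NULL) {
  f <- as.numeric(species_fractions)
  if (length(f) != ncol(extinction_matrix))
    stop("`species_fractions` must have one entry per extinction column",
         call. = FALSE)
  if (any(f < 0) || abs(sum(f) - 1) > 1e-8)
    stop("species fractions must be nonnegative and sum to 1",
         call. = FALSE)
  if (total_hb < 0) stop("`total_hb` must be nonnegative", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)

  od <- as.numeric(pathlength * total_hb * (extinction_matrix %*% f)) +
    turbidity_offset
  names(od) <- rownames(extinction_matrix)
  od <- c(od, "700" = turbidity_offset)
  if (noise_sd > 0) od <- od + stats::rnorm(length(od), 0, noise_sd)
  od <- pmax(od, 0)
  structure(list(od = od, dilution_factor = dilution_factor, role = role),
            class = "absorbance_spectrum")
}

# Pull OD values at requested wavelengths from a spectrum (class object,
# named vector, or data.frame(wavelength_nm, od)).
spectrum_od <- function(spectrum, wavelengths) {
  od <- if (inherits(spectrum, "absorbance_spectrum")) spectrum$od
  else if (is.data.frame(spectrum))
    stats::setNames(spectrum$od, spectrum$wavelength_nm)
  else spectrum
  key <- as.character(wavelengths)
  if (!all(key %in% names(od)))
    stop("spectrum lacks wavelength(s): ",
         paste(setdiff(key, names(od)), collapse = ", "), call. = FALSE)
  as.numeric(od[key])
}

#' Free hemoglobin as percent of the whole-blood lysate signal
#'
#' Quantifies hemolysis from the hemoglobin released into the
#' supernatant: the turbidity-corrected 540 nm absorbance of the
#' supernatant, scaled by its dilution, is expressed as a percentage of
#' the same quantity for the fully lysed whole-blood reference (taken as
#' 100%). The 700 nm read is subtracted at both ends to remove the
#' contribution of solution turbidity.
#'
#' @param supernatant,lysate `absorbance_spectrum` objects (or named OD
#'   vectors) containing 540 and 700 nm.
#' @param supernatant_dilution,lysate_dilution Dilution factors; default
#'   to those recorded in the spectra (1 for bare vectors).
#' @return Free hemoglobin (%), clamped at 0.
#' @export
free_hb_percent <- function(supernatant, lysate,
                            supernatant_dilution = NULL,
                            lysate_dilution = NULL) {
  dil <- function(sp, override) {
    if (!is.null(override)) return(override)
    if (inherits(sp, "absorbance_spectrum")) sp$dilution_factor else 1
  }
  corr <- function(sp) diff(-spectrum_od(sp, c(540, 700)))  # A540 - A700
  sup <- corr(supernatant) * dil(supernatant, supernatant_dilution)
  lys <- corr(lysate) * dil(lysate, lysate_dilution)
  if (lys <= 0)
    stop("lysate corrected OD at 540 nm is not positive: no reference ",
         "hemoglobin signal", call. = FALSE)
  max(0, 100 * sup / lys)
}

#' Hemoglobin species fractions by nonnegative spectral unmixing
#'
#' Subtracts the 700 nm turbidity baseline, then solves the
#' Beer-Lambert system `extinction %*% concentrations = OD` for
#' nonnegative concentrations by NNLS and normalizes them to fractions.
#' NNLS rather than an exact solve keeps noisy spectra from returning
#' negative species; on noiseless data the two coincide whenever the
#' exact solution is nonnegative.
#'
#' @param spectrum `absorbance_spectrum` (or named OD vector /
#'   `data.frame(wavelength_nm, od)`) covering `wavelengths` and 700 nm.
#' @param extinction_matrix Extinction table with rows for
#'   `wavelengths`; see [default_extinction_matrix()].
#' @param wavelengths Wavelengths used for the fit (default
#'   560, 577, 630 nm).
#' @return Object of class `hb_species_result`: list with `fractions`
#'   (named, summing to 1), `concentrations` (same units as the
#'   extinction table's inverse), and `residual` (Euclidean norm).
#' @export
hb_species_fractions <- function(spectrum,
                                 extinction_matrix =
                                   default_extinction_matrix(),
                                 wavelengths = c(560, 577, 630)) {
  key <- as.character(wavelengths)
  if (!all(key %in% rownames(extinction_matrix)))
    stop("extinction matrix lacks row(s): ",
         paste(setdiff(key, rownames(extinction_matrix)), collapse = ", "),
         call. = FALSE)
  E <- extinction_matrix[key, , drop = FALSE]
  if (kappa(E, exact = TRUE) > 1e6)
    stop("extinction matrix is ill-conditioned (condition number > 1e6)",
         call. = FALSE)
  a <- spectrum_od(spectrum, wavelengths) - spectrum_od(spectrum, 700)
  if (all(abs(a) < 1e-12))
    stop("corrected spectrum is all zero: no hemoglobin signal",
         call. = FALSE)
  fit <- pracma::lsqnonneg(E, a)
  conc <- as.numeric(fit$x)
  names(conc) <- colnames(E)
  total <- sum(conc)
  if (total <= 0)
    stop("unmixing returned no nonnegative hemoglobin signal",
         call. = FALSE)
  structure(list(fractions = conc / total,
                 concentrations = conc,
                 residual = sqrt(sum((E %*% conc - a)^2))),
            class = "hb_species_result")
}

#' @export
print.hb_species_result <- function(x, ...) {
  cat("Hemoglobin species fractions:\n")
  print(round(x$fractions, 4))
  cat("residual norm:", format(x$residual, digits = 4), "\n")
  invisible(x)
}
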