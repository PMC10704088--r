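# Whole-blood hemoglobin absorption table compiled from the bundled
# extinction fixture.

# Blood composition constants: hematocrit and mean cell hemoglobin
# concentration (g/L RBC) give the whole-blood hemoglobin concentration.
HEMATOCRIT <- 0.43
MCHC_G_PER_L <- 345
HB_MOLAR_MASS <- 64500  # g/mol, hemoglobin tetramer

#' Compile the whole-blood hemoglobin absorption table
#'
#' Reads the bundled extinction fixture (decadic molar extinction of oxy-
#' and deoxyhemoglobin on a coarse anchor grid), interpolates `log(eps)`
#' with a monotone piecewise cubic (pchip) onto a 1 nm grid, and converts
#' to natural-log whole-blood absorption coefficients assuming hematocrit
#' 43% and a mean cell hemoglobin concentration of 345 g/L RBC
#' (148.35 g/L of blood, i.e. 2.30e-3 mol/L):
#' `mu_a (mm^-1) = ln(10) * eps (cm^-1/M) * C_molar / 10`.
#'
#' @param path Fixture path; defaults to the table shipped with the package
#'   (a synthetic stand-in of realistic shape, see the fixture header).
#' @param grid_nm Output wavelength grid spacing (nm), default 1.
#' @return An object of class `hemoglobin_table` with fields `wavelengths`
#'   (nm), `mu_a_oxy` and `mu_a_deoxy` (mm^-1), `conversion_factor`
#'   (mm^-1 per cm^-1/M) and `concentration_g_per_L`.
#' @export
compile_hemoglobin_table <- function(path = NULL, grid_nm = 1) {
  if (is.null(path))
    path <- system.file("extdata", "hemoglobin_extinction_synthetic.tsv",
                        package = "skindrs")
  if (!nzchar(path) || !file.exists(path))
    stop("hemoglobin extinction fixture not found: configuration error")
  raw <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  stopifnot(all(c("wavelength_nm", "eps_oxy", "eps_deoxy") %in% names(raw)),
            all(diff(raw$wavelength_nm) > 0),
            all(raw$eps_oxy > 0), all(raw$eps_deoxy > 0))
  conc <- HEMATOCRIT * MCHC_G_PER_L            # 148.35 g/L blood
  c_molar <- conc / HB_MOLAR_MASS              # mol/L
  # decadic cm^-1 -> natural-log mm^-1
  k <- log(10) * c_molar / 10
  wl <- seq(min(raw$wavelength_nm), max(raw$wavelength_nm), by = grid_nm)
  oxy <- exp(pracma::pchip(raw$wavelength_nm, log(raw$eps_oxy), wl))
  deoxy <- exp(pracma::pchip(raw$wavelength_nm, log(raw$eps_deoxy), wl))
  structure(list(wavelengths = wl,
                 mu_a_oxy = k * oxy,
                 mu_a_deoxy = k * deoxy,
                 conversion_factor = k,
                 concentration_g_per_L = conc,
                 source = path),
            class = "hemoglobin_table")
}

#' Construct a hemoglobin table from explicit values
#'
#' Mostly useful for tests; see [compile_hemoglobin_table()] for the
#' bundled-data constructor.
#'
#' @param wavelengths Strictly increasing wavelengths (nm).
#' @param mu_a_oxy,mu_a_deoxy Whole-blood absorption (mm^-1), > 0.
#' @return An object of class `hemoglobin_table`.
#' @export
hemoglobin_table <- function(wavelengths, mu_a_oxy, mu_a_deoxy) {
  stopifnot(all(diff(wavelengths) > 0), all(mu_a_oxy > 0),
            all(mu_a_deoxy > 0), length(wavelengths) == length(mu_a_oxy),
            length(wavelengths) == length(mu_a_deoxy))
  structure(list(wavelengths = wavelengths, mu_a_oxy = mu_a_oxy,
                 mu_a_deoxy = mu_a_deoxy, conversion_factor = NA_real_,
                 concentration_g_per_L = NA_real_, source = "explicit"),
            class = "hemoglobin_table")
}

#' Locate the near-infrared isosbestic wavelength of a hemoglobin table
#'
#' Finds the wavelength in `[window]` where the oxy and deoxy whole-blood
#' spectra cross (absorption independent of saturation).
#'
#' @param table A [hemoglobin_table()].
#' @param window Search window (nm), default `c(650, 900)`.
#' @return Crossing wavelength (nm).
#' @export
isosbestic_wavelength <- function(table, window = c(650, 900)) {
  sel <- table$wavelengths >= window[1] & table$wavelengths <= window[2]
  wl <- table$wavelengths[sel]
  d <- table$mu_a_oxy[sel] - table$mu_a_deoxy[sel]
  i <- which(d[-1] * d[-length(d)] <= 0)[1]
  if (is.na(i)) stop("no isosbestic crossing in the given window")
  # linear root between the bracketing grid points
  wl[i] + (wl[i + 1] - wl[i]) * d[i] / (d[i] - d[i + 1])
}
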