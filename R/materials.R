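#' Default material table for the multi-energy phantom
#'
#' Returns the twelve-material table used by the phantom simulator: five
#' hydroxyapatite (HA) concentrations (50/100/200/400/800 mg/cm^3), three
#' iodine concentrations (5/10/15 mg/mL), three soft-tissue surrogates
#' (adipose, liver, lung) and water. Each material carries a per-bin mean
#' attenuation signature `mu` (arbitrary attenuation units) over the `F = 5`
#' energy bins spanning 7--120 keV.
#'
#' The signatures are constructed, not measured: within each contrast family
#' the signature is `mu_water + c * shape`, linear in concentration `c`, and
#' the two family shapes are rescaled so that the band-integrated attenuation
#' `sum(mu)` of I5 equals that of HA100 and of I10 equals that of HA200
#' exactly. Those engineered pairs are therefore indistinguishable by total
#' attenuation and separable only by spectral shape, which is the hard case
#' the classifier must solve. The normalized HA and iodine shapes have cosine
#' similarity well below 0.99 (iodine retains proportionally more attenuation
#' in the wide 21--120 keV bin, a K-edge-like signature).
#'
#' @return A list of 12 material records, each a list with fields `name`,
#'   `class_id` (1..12), `concentration`, `unit` (`"mg/cm^3"`, `"mg/mL"` or
#'   `""`), and `mu` (numeric length 5).
#' @examples
#' mats <- default_materials()
#' vapply(mats, `[[`, character(1), "name")
#' @export
default_materials <- function() {
  mu_water <- c(0.50, 0.38, 0.33, 0.30, 0.25)
  shape_ha <- c(20, 13, 10, 8, 4) * 1e-4 # per mg/cm^3
  raw_i <- c(100, 45, 30, 24, 60) * 1e-4
  # sum(shape_i) == 20 * sum(shape_ha) makes sum(mu) match for (I5, HA100)
  # and (I10, HA200) identically.
  shape_i <- raw_i * (20 * sum(shape_ha) / sum(raw_i))

  mat <- function(name, class_id, conc, unit, mu) {
    list(name = name, class_id = class_id, concentration = conc,
         unit = unit, mu = mu)
  }
  ha <- function(c_mg, id) {
    mat(paste0("HA", c_mg), id, c_mg, "mg/cm^3", mu_water + c_mg * shape_ha)
  }
  io <- function(c_mg, id) {
    mat(paste0("I", c_mg), id, c_mg, "mg/mL", mu_water + c_mg * shape_i)
  }
  list(
    ha(50, 1L), ha(100, 2L), ha(200, 3L), ha(400, 4L), ha(800, 5L),
    io(5, 6L), io(10, 7L), io(15, 8L),
    mat("adipose", 9L, NA_real_, "", c(0.42, 0.335, 0.295, 0.270, 0.235)),
    mat("liver",  10L, NA_real_, "", c(0.54, 0.410, 0.360, 0.330, 0.270)),
    mat("lung",   11L, NA_real_, "", c(0.15, 0.114, 0.099, 0.090, 0.075)),
    mat("water",  12L, 0, "", mu_water)
  )
}

#' @keywords internal
material_mu_matrix <- function(materials = default_materials()) {
  mus <- vapply(materials, `[[`, numeric(5), "mu")
  colnames(mus) <- vapply(materials, `[[`, character(1), "name")
  mus # 5 x 12, columns ordered by class_id
}

#' Class names for the 13 segmentation classes (0 = background)
#' @param materials material table as returned by [default_materials()]
#' @return character vector of length 13 named by class id 0..12
#' @export
class_names <- function(materials = default_materials()) {
  nm <- c("background", vapply(materials, `[[`, character(1), "name"))
  names(nm) <- as.character(0:12)
  nm
}
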