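#' @useDynLib oofdose, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rlnorm runif setNames cor quantile sd integrate
#' @importFrom utils read.table write.table
"_PACKAGE"

# Common energy grid (MeV) for all packaged coefficient tables.  Spans the
# 0.01-10 MeV range a 6 MV treatment beam and its scatter can populate.
.E_GRID <- c(0.01, 0.015, 0.02, 0.03, 0.04, 0.05, 0.06, 0.08, 0.10, 0.15,
             0.20, 0.30, 0.40, 0.50, 0.60, 0.80, 1.00, 1.25, 1.50, 2.00,
             3.00, 4.00, 5.00, 6.00, 8.00, 10.00)

# Mass attenuation (mu/rho) and mass energy-absorption (muen/rho) tables for
# water, dry air and cortical bone, cm^2/g, transcribed from the standard
# NIST compilations on the grid above (with coherent scattering).
.WATER_MU <- c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837,
               0.1707, 0.1505, 0.1370, 0.1186, 0.1061, 0.09687, 0.08956,
               0.07865, 0.07072, 0.06323, 0.05754, 0.04942, 0.03969, 0.03403,
               0.03031, 0.02770, 0.02429, 0.02219)
.WATER_MUEN <- c(4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223, 0.03190,
                 0.02597, 0.02546, 0.02764, 0.02967, 0.03192, 0.03279,
                 0.03299, 0.03284, 0.03206, 0.03103, 0.02965, 0.02833,
                 0.02608, 0.02281, 0.02066, 0.01915, 0.01806, 0.01658,
                 0.01566)
.AIR_MU <- c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662,
             0.1541, 0.1356, 0.1233, 0.1067, 0.09549, 0.08712, 0.08055,
             0.07074, 0.06358, 0.05687, 0.05175, 0.04447, 0.03581, 0.03079,
             0.02751, 0.02522, 0.02225, 0.02045)
.AIR_MUEN <- c(4.742, 1.334, 0.5389, 0.1537, 0.06833, 0.04098, 0.03041,
               0.02407, 0.02325, 0.02496, 0.02672, 0.02872, 0.02949, 0.02966,
               0.02953, 0.02882, 0.02789, 0.02666, 0.02547, 0.02345, 0.02057,
               0.01870, 0.01740, 0.01647, 0.01525, 0.01450)
.BONE_MU <- c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148, 0.2229,
              0.1855, 0.1480, 0.1309, 0.1113, 0.09908, 0.09022, 0.08332,
              0.07308, 0.06566, 0.05871, 0.05346, 0.04607, 0.03745, 0.03257,
              0.02946, 0.02729, 0.02451, 0.02291)
.BONE_MUEN <- c(26.80, 8.388, 3.601, 1.070, 0.4507, 0.2336, 0.1400, 0.06896,
                0.04585, 0.03183, 0.03003, 0.03032, 0.03069, 0.03073, 0.03052,
                0.02973, 0.02856, 0.02736, 0.02603, 0.02401, 0.02123, 0.01968,
                0.01875, 0.01816, 0.01743, 0.01699)

.AVOGADRO <- 6.02214076e23

#' Construct a photon interaction material
#'
#' A material bundles a mass density, an electrons-per-gram value (used by
#' the transport engine to split total attenuation into interaction
#' channels), and tabulated mass attenuation and mass energy-absorption
#' coefficients on a strictly increasing energy grid.
#'
#' @param name material name.
#' @param density mass density, g/cm^3.
#' @param z_over_a mean ratio of atomic number to mass number (electrons per
#'   atomic mass unit); electrons per gram is `z_over_a * N_A`.
#' @param energy strictly increasing photon energies, MeV, covering at least
#'   0.01-7 MeV.
#' @param mu mass attenuation coefficients mu/rho, cm^2/g.
#' @param muen mass energy-absorption coefficients muen/rho, cm^2/g; must not
#'   exceed `mu` anywhere.
#' @return an object of class `oof_material`.
#' @export
material <- function(name, density, z_over_a, energy, mu, muen) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(density), density > 0,
            length(energy) == length(mu), length(mu) == length(muen))
  if (any(diff(energy) <= 0))
    stop("material '", name, "': energies must be strictly increasing")
  if (min(energy) > 0.01 || max(energy) < 7)
    stop("material '", name, "': energy table must cover [0.01, 7] MeV")
  if (any(mu <= 0) || any(muen <= 0))
    stop("material '", name, "': coefficients must be positive")
  if (any(muen > mu * (1 + 1e-12)))
    stop("material '", name, "': muen/rho exceeds mu/rho")
  structure(list(name = name, density = density, z_over_a = z_over_a,
                 electrons_per_g = z_over_a * .AVOGADRO,
                 energy = energy, mu = mu, muen = muen),
            class = "oof_material")
}

#' @export
print.oof_material <- function(x, ...) {
  cat(sprintf("<oof_material> %s  (rho = %.4g g/cm3, %d energies %.3g-%.3g MeV)\n",
              x$name, x$density, length(x$energy), min(x$energy), max(x$energy)))
  invisible(x)
}

# Klein-Nishina total cross-section per electron, cm^2, E in MeV.
kn_total_cs <- function(energy) {
  a <- energy / 0.51099895
  re2 <- 7.94079e-26          # classical electron radius squared, cm^2
  t1 <- (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a)
  t2 <- log(1 + 2 * a) / (2 * a)
  t3 <- (1 + 3 * a) / (1 + 2 * a)^2
  2 * pi * re2 * (t1 + t2 - t3)
}

# Klein-Nishina energy-transfer cross-section per electron (quadrature of the
# energy-weighted differential cross-section), cm^2.
kn_transfer_cs <- function(energy) {
  vapply(energy, function(E) {
    a <- E / 0.51099895
    eps0 <- 1 / (1 + 2 * a)
    f <- function(eps) {
      ct <- 1 - (1 - eps) / (a * eps)
      s2 <- pmax(0, 1 - ct^2)
      (1 / eps + eps) * (1 - eps * s2 / (1 + eps^2)) * (1 - eps)
    }
    # dsigma/deps up to the common constant pi*re2/a; constant restored below
    v <- integrate(f, eps0, 1, rel.tol = 1e-9)$value
    pi * 7.94079e-26 / a * v
  }, numeric(1))
}

# Build a near-water tissue by electron-density scaling of the water tables.
.scaled_tissue <- function(name, density, z_over_a, muen_scale = NULL) {
  f <- z_over_a / 0.55509
  mu <- .WATER_MU * f
  muen <- .WATER_MUEN * f
  if (!is.null(muen_scale)) {
    mu <- mu * muen_scale
    muen <- muen * muen_scale
  }
  material(name, density, z_over_a, .E_GRID, mu, muen)
}

# Smooth, edge-free tungsten-alloy parametrization: Klein-Nishina Compton,
# an E^-3 photoelectric power law and a logarithmic pair term.  Backs the
# collimator attenuation surrogate only.
.tungsten_alloy <- function() {
  za <- 0.4061                          # 95% W / 3.5% Ni / 1.5% Fe by mass
  epg <- za * .AVOGADRO
  compt <- epg * kn_total_cs(.E_GRID)
  compt_tr <- epg * kn_transfer_cs(.E_GRID)
  pe <- 4.32 * (.E_GRID / 0.10)^-3      # anchored near 4.4 cm^2/g at 100 keV
  pair <- ifelse(.E_GRID > 1.022, 0.014 * log(.E_GRID / 1.022)^1.5, 0)
  mu <- compt + pe + pair
  muen <- compt_tr + pe + pair * pmax(0, (.E_GRID - 1.022) / .E_GRID)
  material("tungsten_alloy", 18.0, za, .E_GRID, mu, pmin(muen, mu))
}

#' Packaged material library
#'
#' Returns the bundled photon-interaction materials: air, water, soft tissue,
#' brain, bone (cortical), lung (inflated), thyroid tissue, and a tungsten
#' alloy for collimator attenuation.  Water, air and bone are transcribed
#' standard reference tables; the near-water tissues are electron-density
#' scaled water (accurate at megavoltage energies for these tissues), with the
#' thyroid table anchored so its 6 MeV muen/rho equals the bundled
#' organ-conversion value 0.0194 cm^2/g.
#'
#' @return named list of `oof_material` objects.
#' @export
material_library <- function() {
  soft <- .scaled_tissue("soft_tissue", 1.06, 0.54996)
  # anchor thyroid muen/rho at the 6 MeV node to the bundled conversion value
  i6 <- match(6, .E_GRID)
  base6 <- .WATER_MUEN[i6] * 0.54977 / 0.55509
  ramp <- pmax(0, log(.E_GRID / 1.0)) / log(6 / 1.0)
  scale <- 1 + (0.0194 / base6 - 1) * pmin(1, ramp)
  thy <- .scaled_tissue("thyroid", 1.05, 0.54977)
  thy$mu <- thy$mu * scale
  thy$muen <- thy$muen * scale
  thy$muen[i6] <- 0.0194
  thy <- material("thyroid", 1.05, 0.54977, .E_GRID, thy$mu, thy$muen)
  list(
    air = material("air", 0.0012048, 0.49919, .E_GRID, .AIR_MU, .AIR_MUEN),
    water = material("water", 1.0, 0.55509, .E_GRID, .WATER_MU, .WATER_MUEN),
    soft_tissue = soft,
    brain = .scaled_tissue("brain", 1.04, 0.55239),
    bone = material("bone", 1.92, 0.51478, .E_GRID, .BONE_MU, .BONE_MUEN),
    lung = .scaled_tissue("lung", 0.26, 0.54965),
    thyroid = thy,
    tungsten_alloy = .tungsten_alloy()
  )
}

#' Look up a single material by name
#' @param name one of the names returned by [material_library()].
#' @return an `oof_material`.
#' @export
get_material <- function(name) {
  lib <- material_library()
  if (!name %in% names(lib))
    stop("unknown material '", name, "'; available: ",
         paste(names(lib), collapse = ", "))
  lib[[name]]
}

#' Interpolate a packaged coefficient at an arbitrary energy
#'
#' Log-log interpolation between the bracketing tabulated energies; queries
#' exactly at a tabulated energy return the tabulated value.  No
#' extrapolation: energies outside the table range are an error.
#'
#' @param material an `oof_material`.
#' @param energy photon energy, MeV.
#' @param which `"mu"` (mass attenuation) or `"muen"` (mass energy
#'   absorption), both cm^2/g.
#' @return coefficient in cm^2/g (vectorized over `energy`).
#' @export
coefficient_at <- function(material, energy, which = c("mu", "muen")) {
  which <- match.arg(which)
  stopifnot(inherits(material, "oof_material"))
  e <- material$energy
  if (any(energy < min(e)) || any(energy > max(e)))
    stop("energy outside the tabulated range [", min(e), ", ", max(e),
         "] MeV for material '", material$name, "' (no extrapolation)")
  y <- material[[which]]
  exp(approx(log(e), log(y), xout = log(energy), method = "linear")$y)
}

#' Organ conversion table for the TLD tissue-dose step
#'
#' Per-organ mass energy-absorption coefficients at the 6 MeV conversion
#' energy, together with the phantom-section and dosimeter layout used in the
#' measurement campaign this package models (two groups of 38 TLDs).
#'
#' @return data.frame with columns `organ`, `muen_rho` (cm^2/g at 6 MeV),
#'   `n_sections`, `n_tlds`.
#' @export
organ_conversion_table <- function() {
  data.frame(
    organ = c("right_eye", "left_eye", "c_spine", "thyroid", "heart",
              "right_lung", "left_lung"),
    muen_rho = c(0.0179, 0.0179, 0.0179, 0.0194, 0.0179, 0.0179, 0.0179),
    n_sections = c(1L, 1L, 2L, 2L, 2L, 5L, 5L),
    n_tlds = c(1L, 1L, 2L, 4L, 2L, 12L, 16L),
    stringsAsFactors = FALSE
  )
}

#' @importFrom stats approx
NULL
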