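# R-level surface of the Monte Carlo transport engine: source and
# collimation models, beam-frame geometry, tally post-processing, reference
# calibration and whole-plan simulation.

#' Parametric 6 MV photon spectrum
#'
#' Discrete bremsstrahlung-like spectrum p(E) proportional to E exp(-E/0.9)
#' on 0.25-6 MeV (mean about 1.8 MeV), a standard desk-scale surrogate for a
#' tuned linac target spectrum.
#'
#' @return data.frame with `energy` (MeV) and `prob` (sums to 1).
#' @export
default_spectrum <- function() {
  e <- seq(0.25, 6, by = 0.25)
  p <- e * exp(-e / 0.9)
  data.frame(energy = e, prob = p / sum(p))
}

#' Photon source model
#'
#' A point-like bremsstrahlung source 100 cm upstream of the isocenter along
#' the beam axis, with a Gaussian focal spot and either the packaged 6 MV
#' spectrum or a monoenergetic line (useful for physics tests).
#'
#' One source particle is one photon emitted into the maximum collimated
#' cone (`cone_area` at the isocenter plane).  Photons are importance-sampled
#' onto the jaw rectangle plus margin and carry the area fraction as weight,
#' which makes per-particle tallies - and hence the reference conversion
#' factor - transferable across field sizes.
#'
#' @param spectrum `"6mv"`, a single energy in MeV, or a data.frame with
#'   `energy`/`prob` columns.
#' @param focal_fwhm_cm focal spot full width at half maximum, cm.
#' @param sad source-axis distance, cm.
#' @param cone_area area of the maximum collimated field at the isocenter
#'   plane, cm^2 (40 x 40 cm).
#' @return an `oof_source`.
#' @export
source_model <- function(spectrum = "6mv", focal_fwhm_cm = 0.12, sad = 100,
                         cone_area = 1600) {
  if (is.character(spectrum)) {
    stopifnot(spectrum == "6mv")
    sp <- default_spectrum()
  } else if (is.numeric(spectrum) && length(spectrum) == 1L) {
    sp <- data.frame(energy = spectrum, prob = 1)
  } else {
    sp <- as.data.frame(spectrum)
    stopifnot(all(c("energy", "prob") %in% names(sp)))
    sp$prob <- sp$prob / sum(sp$prob)
  }
  if (any(sp$energy <= 0.01) || any(sp$energy > 7))
    stop("spectrum energies must lie in (0.01, 7] MeV")
  if (abs(sum(sp$prob) - 1) > 1e-9) stop("spectrum probabilities must sum to 1")
  structure(list(spectrum = sp, focal_fwhm_cm = focal_fwhm_cm, sad = sad,
                 cone_area = cone_area),
            class = "oof_source")
}

#' Collimation surrogate
#'
#' Parametric replacement for the full treatment head: photons geometrically
#' blocked by the MLC or jaws carry the respective transmission fraction as
#' statistical weight, and a configurable fraction of histories is emitted
#' isotropically from the target as head leakage.  Defaults are typical
#' published values for this linac class.
#'
#' @param mlc_transmission,jaw_transmission transmitted weight fractions in
#'   `[0, 1)`.
#' @param head_leakage fraction of primary fluence emitted isotropically.
#' @param sampling_margin cm of margin around the jaw rectangle over which
#'   primary photons are aimed (captures penumbra and collimator-transmission
#'   fluence).
#' @return an `oof_collimation`.
#' @export
collimation_model <- function(mlc_transmission = 0.017,
                              jaw_transmission = 0.002,
                              head_leakage = 0.001,
                              sampling_margin = 3) {
  fr <- c(mlc_transmission, jaw_transmission, head_leakage)
  if (any(fr < 0) || any(fr >= 1))
    stop("transmission and leakage fractions must lie in [0, 1)")
  if (jaw_transmission > mlc_transmission)
    warning("jaw_transmission > mlc_transmission: jaws are normally the ",
            "more opaque collimator")
  structure(list(mlc_transmission = mlc_transmission,
                 jaw_transmission = jaw_transmission,
                 head_leakage = head_leakage,
                 sampling_margin = sampling_margin),
            class = "oof_collimation")
}

#' Transport configuration
#'
#' @param n_histories number of source histories.
#' @param batches number of statistical batches (>= 10 for a meaningful
#'   standard-error estimate).
#' @param seed integer random seed.
#' @param photon_cutoff photon energy cutoff, MeV.
#' @param rr_weight_threshold weight below which Russian roulette is played.
#' @param rr_survival survival probability; survivors have their weight
#'   divided by this, keeping the game unbiased.
#' @param split_factor integer; particles are split into this many copies at
#'   birth (1 = no splitting).
#' @param absorption_only if `TRUE`, every real interaction deposits the full
#'   photon energy locally (closed-form attenuation test mode).
#' @return an `oof_transport_config`.
#' @export
transport_config <- function(n_histories = 1e5, batches = 20L, seed = 1L,
                             photon_cutoff = 0.01,
                             rr_weight_threshold = 0.05, rr_survival = 0.2,
                             split_factor = 1L, absorption_only = FALSE) {
  if (photon_cutoff < 0.01)
    stop("photon_cutoff below the 0.01 MeV table floor")
  if (batches < 2) stop("need at least 2 batches")
  structure(list(n_histories = n_histories, batches = as.integer(batches),
                 seed = as.integer(seed), photon_cutoff = photon_cutoff,
                 rr_weight_threshold = rr_weight_threshold,
                 rr_survival = rr_survival,
                 split_factor = as.integer(split_factor),
                 absorption_only = isTRUE(absorption_only)),
            class = "oof_transport_config")
}

.rot_z <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}
.rot_y <- function(th) {
  c <- cos(th); s <- sin(th)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Beam frame from plan angles
#'
#' Patient axes: x to the patient's left, y anterior, z superior; isocenter
#' at the origin.  At gantry/couch/collimator zero the source sits on +y and
#' the beam travels along -y, with the collimator x axis along patient x and
#' the collimator y axis along patient z.  The gantry rotates the source
#' about the patient z axis (gantry 90 places the source at the patient's
#' left); the couch kick rotates the beam about the vertical y axis (sign
#' chosen so the packaged non-coplanar brain fields enter superiorly, away
#' from the orbits); the
#' collimator spins the aperture about the beam axis.
#'
#' @param gantry,couch,collimator angles, degrees.
#' @param sad source-axis distance, cm.
#' @return list with source position `S` and orthonormal `u`, `v`
#'   (collimator axes at the isocenter plane) and `w` (beam direction).
#' @export
beam_frame <- function(gantry, couch = 0, collimator = 0, sad = 100) {
  d2r <- pi / 180
  R <- .rot_y(-couch * d2r) %*% .rot_z(-gantry * d2r)
  w <- as.numeric(R %*% c(0, -1, 0))
  u <- as.numeric(R %*% c(1, 0, 0))
  v <- as.numeric(R %*% c(0, 0, 1))
  if (collimator != 0) {
    k <- collimator * d2r
    rot_about <- function(a, axis, th) {
      axis <- axis / sqrt(sum(axis^2))
      a * cos(th) + pracma_cross(axis, a) * sin(th) +
        axis * sum(axis * a) * (1 - cos(th))
    }
    u2 <- rot_about(u, w, k)
    v <- rot_about(v, w, k)
    u <- u2
  }
  list(S = -sad * w, u = u, v = v, w = w)
}

# minimal cross product (avoids a dependency for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- packing helpers (R structures -> flat lists for the C++ core) --------

.pack_materials <- function(materials) {
  nm <- length(materials)
  grid <- materials[[1]]$energy
  log_mu <- matrix(0, nm, length(grid))
  log_muen <- matrix(0, nm, length(grid))
  density <- e_per_g <- pe_coef <- numeric(nm)
  for (i in seq_len(nm)) {
    m <- materials[[i]]
    stopifnot(identical(m$energy, grid))
    log_mu[i, ] <- log(m$mu)
    log_muen[i, ] <- log(m$muen)
    density[i] <- m$density
    e_per_g[i] <- m$electrons_per_g
    mu03 <- coefficient_at(m, 0.03, "mu")
    pe_coef[i] <- max(0, mu03 - m$electrons_per_g * kn_total_cs(0.03)) *
      0.03^3
  }
  mumaj <- apply(exp(log_mu) * density, 2, max) * 1.05
  list(log_energy = log(grid), log_mu = log_mu, log_muen = log_muen,
       density = density, e_per_g = e_per_g, pe_coef = pe_coef,
       log_mumaj = log(mumaj))
}

.pack_grid <- function(phantom) {
  list(dims = as.integer(phantom$dims),
       voxel_size = as.numeric(phantom$voxel_size),
       origin = as.numeric(phantom$origin),
       material_index = as.integer(phantom$material_index),
       organ_label = as.integer(phantom$organ_label),
       n_labels = length(phantom$label_names))
}

.pack_source <- function(source, collimation, aperture, frame) {
  sp <- source$spectrum
  jaw <- aperture$jaw
  m <- collimation$sampling_margin
  strips <- aperture$strips
  if (is.null(strips)) {
    strips_m <- matrix(0, 0, 4)
    has_mlc <- FALSE
  } else {
    strips_m <- as.matrix(strips[, c("y_lo", "y_hi", "x_lo", "x_hi")])
    has_mlc <- TRUE
  }
  bbox <- c(jaw[1] - m, jaw[2] + m, jaw[3] - m, jaw[4] + m)
  list(spec_energy = sp$energy, spec_cdf = cumsum(sp$prob),
       focal_sigma = source$focal_fwhm_cm / 2.3548,
       S = frame$S, u = frame$u, v = frame$v, w = frame$w,
       bbox = bbox,
       area_scale = (bbox[2] - bbox[1]) * (bbox[4] - bbox[3]) /
         source$cone_area,
       jaw = jaw, strips = strips_m, has_mlc = has_mlc,
       t_mlc = collimation$mlc_transmission,
       t_jaw = collimation$jaw_transmission,
       leak = collimation$head_leakage)
}

.pack_config <- function(config) {
  c(unclass(config), list(vr_enabled = TRUE))
}

#' Sample photons from the collimated source
#'
#' Primary photons are aimed at points covering the jaw rectangle plus the
#' sampling margin at the isocenter plane; geometrically blocked photons
#' carry the relevant transmission as weight, and a `head_leakage` fraction
#' of histories is emitted isotropically from the target.
#'
#' @param n number of photons.
#' @param source an `oof_source`.
#' @param collimation an `oof_collimation`.
#' @param aperture an `oof_aperture` from [aperture_at()].
#' @param frame a beam frame from [beam_frame()].
#' @param seed integer seed.
#' @return data.frame with position, direction, energy and statistical
#'   weight per photon.
#' @export
sample_source_photon <- function(n, source, collimation, aperture,
                                 frame = beam_frame(0), seed = 1L) {
  m <- cpp_sample_source(as.integer(n),
                         .pack_source(source, collimation, aperture, frame),
                         as.numeric(seed))
  as.data.frame(m)
}

#' Sample Klein-Nishina Compton scattering
#'
#' @param n number of draws.
#' @param energy incident photon energy, MeV.
#' @param seed integer seed.
#' @return data.frame with scattered `energy` (MeV) and `cos_theta`.
#' @export
sample_compton <- function(n, energy, seed = 1L) {
  stopifnot(energy > 0)
  as.data.frame(cpp_sample_compton(as.integer(n), energy, as.numeric(seed)))
}

#' Pencil-beam slab experiment
#'
#' Fires a monoenergetic pencil beam at a homogeneous slab and returns
#' per-batch transmitted (never-collided) weight fraction plus deposited and
#' escaping energy per history - the closed-form attenuation, energy
#' conservation and variance-reduction test bench.
#'
#' @param material_name a material from [material_library()].
#' @param energy MeV.
#' @param thickness slab thickness, cm.
#' @param config an [transport_config()].
#' @param init_weights,init_probs discrete distribution of initial weights.
#' @param vr_enabled apply Russian roulette / splitting at birth.
#' @return list of per-batch vectors `transmitted`, `deposited`, `escaped`,
#'   `initial`.
#' @export
pencil_slab <- function(material_name, energy, thickness, config,
                        init_weights = 1, init_probs = 1,
                        vr_enabled = FALSE) {
  lib <- material_library()
  idx <- match(material_name, names(lib))
  if (is.na(idx)) stop("unknown material '", material_name, "'")
  mats <- .pack_materials(lib)
  cfg <- c(unclass(config), list(vr_enabled = isTRUE(vr_enabled)))
  cpp_pencil_slab(config$n_histories, config$batches, energy, thickness,
                  mats, idx, init_weights, init_probs, cfg,
                  as.numeric(config$seed))
}

#' Run one beam on a phantom
#'
#' Transports `n_histories` photons of one field (static jaw aperture or one
#' MLC control point) through the phantom and returns per-organ mean dose
#' per source particle (MeV/g) with batch-based relative standard errors.
#'
#' @param phantom an `oof_phantom`.
#' @param field one row of a plan `fields` table.
#' @param source an `oof_source`.
#' @param collimation an `oof_collimation`.
#' @param config an `oof_transport_config`.
#' @param cp optional MLC control point (list with `bank_a`, `bank_b`).
#' @return data.frame (class `oof_tally`) with `organ`, `dose_per_particle`
#'   (MeV/g), `rel_se`, `nonzero_batches`, `se_defined`; attributes
#'   `histories`, `batches`.
#' @export
run_beam <- function(phantom, field, source, collimation, config,
                     cp = NULL) {
  aperture <- aperture_at(field, cp)
  frame <- beam_frame(field$gantry, field$couch, field$collimator,
                      sad = source$sad)
  res <- cpp_run_beam(.pack_grid(phantom),
                      .pack_materials(phantom$materials),
                      .pack_source(source, collimation, aperture, frame),
                      .pack_config(config))
  tally <- res$tally
  organs <- names(phantom$label_names)
  vol <- vapply(organs, function(o) organ_volume(phantom, o)$volume_cm3,
                numeric(1))
  per_batch <- tally / vol            # rows = labels, recycled by column
  means <- rowMeans(per_batch)
  nb <- ncol(per_batch)
  se <- apply(per_batch, 1, sd) / sqrt(nb)
  nonzero <- apply(per_batch, 1, function(x) sum(x > 0))
  out <- data.frame(organ = organs,
                    dose_per_particle = means,
                    rel_se = ifelse(means > 0, se / means, NA_real_),
                    nonzero_batches = nonzero,
                    se_defined = nonzero >= 2,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "histories") <- res$histories_per_batch * nb
  attr(out, "batches") <- nb
  class(out) <- c("oof_tally", "data.frame")
  out
}

#' Reference-condition conversion factor
#'
#' Simulates the reference geometry - water phantom with its surface at the
#' isocenter (SSD 100 cm), 10 x 10 cm field with the MLC retracted - and
#' returns the factor CF that maps a tally (MeV/g per source particle) to
#' absolute dose, such that the reference scoring volume at the calibration
#' depth receives `cal_dose_mgy_per_mu` mGy per monitor unit.
#'
#' @param source an `oof_source`.
#' @param collimation an `oof_collimation`.
#' @param config an `oof_transport_config`.
#' @param cal_dose_mgy_per_mu calibration dose at the reference point,
#'   mGy/MU.
#' @param depth_cm reference scoring depth in water, cm.
#' @return list with `cf` (mGy per MU per tally unit), `ref_tally`,
#'   `ref_rel_se` and the geometry descriptor.
#' @export
calibrate_cf <- function(source, collimation, config,
                         cal_dose_mgy_per_mu = 10, depth_cm = 10) {
  ref <- organ_spec("refpoint", "ellipsoid", c(1.5, 0.75, 1.5),
                    c(0, -depth_cm, 0), material = "water", is_target = TRUE)
  body <- organ_spec("water_tank", "box", c(15, 15, 15), c(0, -15, 0),
                     material = "water")
  ph <- build_phantom(list(ref), body, dims = c(62L, 62L, 62L),
                      voxel_size = c(0.5, 0.5, 0.5))
  field <- list(field_id = "ref", gantry = 0, collimator = 0, couch = 0,
                x1 = 5, x2 = 5, y1 = 5, y2 = 5)
  tal <- run_beam(ph, field, source, collimation, config)
  t_ref <- tal$dose_per_particle[tal$organ == "refpoint"]
  if (!is.finite(t_ref) || t_ref <= 0)
    stop("zero reference tally: cannot calibrate")
  list(cf = cal_dose_mgy_per_mu / t_ref,
       ref_tally = t_ref,
       ref_rel_se = tal$rel_se[tal$organ == "refpoint"],
       geometry = sprintf("10x10 cm, SSD %g cm, depth %g cm, %g mGy/MU",
                          source$sad, depth_cm, cal_dose_mgy_per_mu))
}

#' Simulate a full treatment plan
#'
#' Expands the plan into its job list (one static job per 3DCRT field; one
#' job per subsampled MLC control point for IMRT), runs each job with
#' `config$n_histories` histories, and accumulates absolute organ doses:
#' dose = sum over jobs of tally x CF x job MU, times the number of
#' prescribed fractions.  Per-job statistical errors combine in quadrature.
#'
#' @param phantom an `oof_phantom`.
#' @param plan an `oof_plan`.
#' @param source an `oof_source`.
#' @param collimation an `oof_collimation`.
#' @param config an `oof_transport_config` (histories are per job).
#' @param cf conversion factor from [calibrate_cf()] (the `cf` element, or
#'   the full list).
#' @param step control-point subsampling stride for dynamic fields.
#' @return data.frame (class `oof_dose_report`) with `organ`, `dose_mGy`,
#'   `se_mGy`; attributes `technique`, `fractions`, `jobs`.
#' @export
simulate_plan <- function(phantom, plan, source, collimation, config, cf,
                          step = 5L) {
  if (is.list(cf)) cf <- cf$cf
  jobs <- plan_jobs(plan, step)
  fractions <- plan$prescription$total_gy / plan$prescription$per_fraction_gy
  organs <- names(phantom$label_names)
  dose <- se2 <- setNames(numeric(length(organs)), organs)
  for (j in seq_len(nrow(jobs))) {
    fid <- jobs$field_id[j]
    field <- plan$fields[plan$fields$field_id == fid, ]
    cp <- NULL
    if (!is.na(jobs$cp_index[j])) {
      seqi <- plan$mlc_sequences[[fid]]
      row <- match(jobs$cp_index[j], seqi$index)
      cp <- list(bank_a = seqi$bank_a[row, ], bank_b = seqi$bank_b[row, ])
    }
    cfg <- config
    cfg$seed <- config$seed + j           # independent stream per job
    tal <- run_beam(phantom, field, source, collimation, cfg, cp)
    scale <- cf * jobs$mu[j] * fractions
    dpp <- tal$dose_per_particle
    abs_se <- ifelse(is.na(tal$rel_se), 0, tal$rel_se * dpp)
    dose <- dose + dpp * scale
    se2 <- se2 + (abs_se * scale)^2
  }
  out <- data.frame(organ = organs, dose_mGy = as.numeric(dose),
                    se_mGy = sqrt(as.numeric(se2)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "technique") <- plan$technique
  attr(out, "fractions") <- fractions
  attr(out, "jobs") <- nrow(jobs)
  class(out) <- c("oof_dose_report", "data.frame")
  out
}
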