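# Synthetic-data generators: TLD reading tables consistent with the
# reduction chain and its uncertainty budget, dynamic MLC log files with the
# clinical moving-pair structure, and the packaged plan fixtures - so every
# stage of the pipeline is testable without external data.

#' Bundled reference organ-dose table (TLD measurements)
#'
#' Published mean out-of-field organ doses and their reported SDs from the
#' TLD measurement campaign this package models: a 54 Gy pediatric brain
#' course delivered with both techniques, organs ordered by center-to-center
#' distance from the target (right eye 6.2 cm through left lung 23.3 cm).
#' These are measured inputs for the comparison stage and generator truths -
#' not outputs of the simulator.
#'
#' @return data.frame with `organ`, `distance_cm`, `dose_3dcrt_mGy`,
#'   `sd_3dcrt_mGy`, `dose_imrt_mGy`, `sd_imrt_mGy`.
#' @export
tld_reference_doses <- function() {
  data.frame(
    organ = c("right_eye", "left_eye", "c_spine", "thyroid", "right_lung",
              "heart", "left_lung"),
    distance_cm = c(6.2, 8.4, 11.1, 13.1, 21.7, 22.2, 23.3),
    dose_3dcrt_mGy = c(593.0, 475.2, 180.9, 69.7, 28.0, 25.2, 19.8),
    sd_3dcrt_mGy = c(93.7, 75.1, 28.6, 11.0, 4.4, 4.0, 3.1),
    dose_imrt_mGy = c(13040.6, 6525.3, 182.3, 79.4, 37.4, 30.6, 27.1),
    sd_imrt_mGy = c(2060.4, 1031.0, 28.8, 12.5, 5.9, 4.8, 4.3),
    stringsAsFactors = FALSE
  )
}

#' Generator configuration for synthetic TLD readings
#'
#' @param true_doses named numeric: true organ doses, mGy.  Defaults to the
#'   bundled reference means for the chosen technique (set when generating).
#' @param n_dosimeters named integer: dosimeters per organ; defaults to the
#'   clinical layout (1, 1, 2, 4, 2, 12, 16 = 38 per technique).
#' @param noise_rel relative standard deviation of the multiplicative
#'   log-normal reading noise; defaults to the combined 15.8% budget.
#' @param ecc_spread relative spread of the per-dosimeter element correction
#'   coefficients around 1 (recorded in the output, so it cancels exactly in
#'   reduction).
#' @param rcf nominal reader calibration factor, reader units per mGy.
#' @param f_q,f_e nominal reader-stability and energy corrections.
#' @param seed integer seed.
#' @return an `oof_generator_config`.
#' @export
generator_config <- function(true_doses = NULL, n_dosimeters = NULL,
                             noise_rel = round(combine_uncertainty(
                               uncertainty_budget()), 1) / 100,
                             ecc_spread = 0.03, rcf = 0.4, f_q = 0.98,
                             f_e = 1.0, seed = 1L) {
  tab <- organ_conversion_table()
  if (is.null(n_dosimeters))
    n_dosimeters <- setNames(tab$n_tlds, tab$organ)
  if (!is.null(true_doses)) {
    unknown <- setdiff(names(true_doses), tab$organ)
    if (length(unknown))
      stop("unknown organ(s) in true_doses: ",
           paste(unknown, collapse = ", "))
    if (any(true_doses < 0)) stop("true doses must be >= 0")
  }
  structure(list(true_doses = true_doses, n_dosimeters = n_dosimeters,
                 noise_rel = noise_rel, ecc_spread = ecc_spread, rcf = rcf,
                 f_q = f_q, f_e = f_e, seed = as.integer(seed)),
            class = "oof_generator_config")
}

#' Generate synthetic TLD readings by inverting the reduction chain
#'
#' For each dosimeter the raw reading is the exact inverse of the reduction
#' chain at the organ's true dose -
#' `RD = D x (muen/rho)_air / (muen/rho)_tissue x RCF / (Ecc f_Q f_E)` -
#' multiplied by unit-mean log-normal noise with relative standard deviation
#' `noise_rel` (so recovered organ means are unbiased).  Per-dosimeter Ecc
#' values are drawn around 1 and recorded in the output, hence cancel in the
#' reduction; in noiseless mode the round trip is exact.
#'
#' In `decomposed` mode the noise is instead applied through the individual
#' calibration factors (Ecc, f_Q, RCF, f_E) with the budget's component
#' spreads, while the recorded factors stay nominal - the mode used to
#' validate that the quadrature budget matches the realized spread.
#'
#' @param config an [generator_config()].
#' @param technique `"3DCRT"` or `"IMRT"`; selects the default truths.
#' @param noiseless if `TRUE`, no noise (exact inverse).
#' @param decomposed apply component-wise factor noise instead of
#'   reading-level noise.
#' @return an `oof_tld_records` table.
#' @export
generate_tld_readings <- function(config = generator_config(),
                                  technique = c("3DCRT", "IMRT"),
                                  noiseless = FALSE, decomposed = FALSE) {
  technique <- match.arg(technique)
  ref <- tld_reference_doses()
  truths <- config$true_doses
  if (is.null(truths)) {
    truths <- setNames(if (technique == "3DCRT") ref$dose_3dcrt_mGy
                       else ref$dose_imrt_mGy, ref$organ)
  }
  tab <- organ_conversion_table()
  air6 <- coefficient_at(get_material("air"), 6, "muen")
  set.seed(config$seed)
  rows <- list()
  comp <- setNames(default_budget_components()$rel_pct / 100,
                   default_budget_components()$name)
  for (organ in names(truths)) {
    n <- config$n_dosimeters[[organ]]
    if (is.null(n) || is.na(n)) stop("no dosimeter count for organ ", organ)
    muen_t <- tab$muen_rho[match(organ, tab$organ)]
    if (is.na(muen_t)) stop("unknown organ '", organ, "'")
    ecc <- exp(rnorm(n, 0, config$ecc_spread))
    k_true <- truths[[organ]] * air6 / muen_t      # true air kerma, mGy
    rd0 <- k_true * config$rcf / (ecc * config$f_q * config$f_e)
    if (noiseless) {
      rd <- rd0
      ecc_rec <- ecc; fq_rec <- config$f_q
      fe_rec <- config$f_e; rcf_rec <- config$rcf
    } else if (decomposed) {
      # true factors differ from the recorded nominal ones component-wise
      unit_ln <- function(n, s) {
        sl <- sqrt(log(1 + s^2))
        rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
      }
      ecc_true <- ecc * unit_ln(n, comp[["element_correction"]])
      fq_true <- config$f_q * unit_ln(n, comp[["reader_stability"]])
      rcf_true <- config$rcf * unit_ln(n, comp[["reader_calibration"]])
      fe_true <- config$f_e * unit_ln(n, comp[["energy_dependence"]])
      rd <- k_true * rcf_true / (ecc_true * fq_true * fe_true)
      ecc_rec <- ecc; fq_rec <- config$f_q
      fe_rec <- config$f_e; rcf_rec <- config$rcf
    } else {
      sl <- sqrt(log(1 + config$noise_rel^2))
      rd <- rd0 * rlnorm(n, meanlog = -sl^2 / 2, sdlog = sl)
      ecc_rec <- ecc; fq_rec <- config$f_q
      fe_rec <- config$f_e; rcf_rec <- config$rcf
    }
    rows[[organ]] <- tld_records(
      dosimeter_id = sprintf("%s_%s_%02d", substr(technique, 1, 2), organ,
                             seq_len(n)),
      organ = organ, technique = technique, rd = rd, ecc = ecc_rec,
      f_q = fq_rec, f_fad = 1, f_e = fe_rec, f_alpha = 1, rcf = rcf_rec)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("oof_tld_records", "data.frame")
  out
}

#' Generate a synthetic dynamic MLC log
#'
#' Sliding-window leaf trajectories: the moving pairs (clinically pairs
#' 27-34, the strips covered by the jaw Y opening) form smooth apertures
#' that sweep across the jaw X range, all other pairs stay parked closed
#' under the jaws, and the cumulative MU fraction increases strictly to 1.
#' Output parses cleanly with [parse_mlc_log()]; a fixed seed gives a
#' byte-identical file.
#'
#' @param field one row of a plan `fields` table.
#' @param n_control_points number of control points.
#' @param moving_pairs integer vector of leaf-pair indices allowed to move.
#' @param seed integer seed.
#' @param file optional output path; if `NULL` a tempfile is used.
#' @param mlc leaf geometry.
#' @return path of the written log file.
#' @export
generate_mlc_log <- function(field, n_control_points = 100L,
                             moving_pairs = 27:34, seed = 1L, file = NULL,
                             mlc = mlc_geometry()) {
  n_pairs <- nrow(mlc)
  if (any(moving_pairs < 1 | moving_pairs > n_pairs))
    stop("moving pairs must lie in 1..", n_pairs)
  if (is.null(file))
    file <- tempfile(paste0("mlclog_", field$field_id, "_"), fileext = ".txt")
  set.seed(seed)
  n <- as.integer(n_control_points)
  x_lo <- -field$x1
  x_hi <- field$x2
  park <- x_lo - 1                       # closed junction parked off-field
  a <- matrix(park, n, n_pairs)
  b <- matrix(park, n, n_pairs)
  t <- seq(0, 1, length.out = n)
  for (p in moving_pairs) {
    # per-pair sweep with a smoothly varying gap width
    w0 <- runif(1, 0.6, 1.5)
    w1 <- runif(1, 0.6, 1.5)
    phase <- runif(1, 0, 2 * pi)
    gap <- (w0 + (w1 - w0) * t) * (0.85 + 0.15 * sin(2 * pi * t + phase))
    centre <- x_lo + (x_hi - x_lo) * (0.1 + 0.8 * t)
    ai <- pmax(x_lo, centre - gap / 2)
    bi <- pmin(x_hi, centre + gap / 2)
    a[, p] <- pmin(ai, bi)
    b[, p] <- pmax(ai, bi)
  }
  mu_fr <- cumsum(runif(n, 0.5, 1.5))
  mu_fr <- mu_fr / mu_fr[n]
  cps <- data.frame(index = seq_len(n), mu_fraction = mu_fr)
  cps$bank_a <- a
  cps$bank_b <- b
  write_mlc_log(cps, field$field_id, file)
  file
}

#' Packaged plan fixtures
#'
#' Paths of the bundled delivery tables for the two techniques: six
#' non-coplanar static brain fields (269 MU) and seven coplanar dynamic
#' fields (334 MU), reproducing every printed cell of the clinical planning
#' tables this package models.
#'
#' @return named list with `plan_3dcrt` and `plan_imrt` file paths.
#' @export
fixture_plans <- function() {
  list(plan_3dcrt = system.file("extdata", "plan_3dcrt.tsv",
                                package = "oofdose", mustWork = TRUE),
       plan_imrt = system.file("extdata", "plan_imrt.tsv",
                               package = "oofdose", mustWork = TRUE))
}

#' Load the packaged plans, generating MLC logs for the dynamic technique
#'
#' @param seed seed for the synthetic MLC logs attached to the IMRT plan.
#' @param n_control_points control points per generated log.
#' @return list with `plan_3dcrt` and `plan_imrt` (`oof_plan` objects).
#' @export
load_fixture_plans <- function(seed = 1L, n_control_points = 100L) {
  paths <- fixture_plans()
  p3 <- parse_plan_table(paths$plan_3dcrt)
  imrt_fields <- parse_plan_table(paths$plan_imrt)$fields
  logs <- list()
  for (i in seq_len(nrow(imrt_fields))) {
    f <- imrt_fields[i, ]
    lf <- generate_mlc_log(f, n_control_points, seed = seed + i)
    logs[[f$field_id]] <- parse_mlc_log(lf)
  }
  pi_ <- treatment_plan("IMRT", imrt_fields, logs)
  list(plan_3dcrt = p3, plan_imrt = pi_)
}
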