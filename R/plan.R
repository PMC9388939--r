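# Plan-table and MLC-log data model: beam fields as parsed from the delivery
# tables (jaw half-openings at the isocenter plane, cm; monitor units per
# field), dynamic-MLC control-point sequences, control-point subsampling into
# a simulation job list, and aperture geometry composition.

.PLAN_COLUMNS <- c("field_id", "gantry", "collimator", "couch", "field_x",
                   "x1", "x2", "field_y", "y1", "y2", "weight", "ssd", "mu")

#' Multileaf collimator geometry
#'
#' 60 opposed leaf pairs stacked along the collimator y axis: 0.5 cm leaves
#' (at isocenter) for the central 40 pairs and 1.0 cm for the 10 outermost
#' pairs on each side (Millennium-120-like), 40 cm total span.
#'
#' @param n_pairs number of leaf pairs.
#' @param central_width,outer_width leaf widths at isocenter, cm.
#' @param n_central number of central (thin) pairs.
#' @return data.frame with `pair`, `y_lo`, `y_hi` (strip extent, cm).
#' @export
mlc_geometry <- function(n_pairs = 60L, central_width = 0.5,
                         outer_width = 1.0, n_central = 40L) {
  n_outer <- (n_pairs - n_central) / 2
  widths <- c(rep(outer_width, n_outer), rep(central_width, n_central),
              rep(outer_width, n_outer))
  hi <- cumsum(widths) - sum(widths) / 2
  data.frame(pair = seq_len(n_pairs), y_lo = hi - widths, y_hi = hi)
}

.validate_fields <- function(df, tol = 0.05) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (abs(r$field_x - (r$x1 + r$x2)) > tol)
      stop(sprintf("field '%s' (row %d): field X %.2f != X1 + X2 = %.2f",
                   r$field_id, i, r$field_x, r$x1 + r$x2))
    if (abs(r$field_y - (r$y1 + r$y2)) > tol)
      stop(sprintf("field '%s' (row %d): field Y %.2f != Y1 + Y2 = %.2f",
                   r$field_id, i, r$field_y, r$y1 + r$y2))
    if (r$mu < 0) stop("field '", r$field_id, "': MU must be >= 0")
    ang <- c(r$gantry, r$collimator, r$couch)
    if (any(ang < 0 | ang >= 360))
      stop("field '", r$field_id, "': angles must lie in [0, 360)")
  }
  invisible(df)
}

#' Assemble a treatment plan
#'
#' @param technique `"3DCRT"` or `"IMRT"`.
#' @param fields data.frame with the plan-table columns
#'   (`field_id, gantry, collimator, couch, field_x, x1, x2, field_y, y1, y2,
#'   weight, ssd, mu`).
#' @param mlc_sequences named list (by `field_id`) of control-point
#'   data.frames from [parse_mlc_log()]; required per field for IMRT.
#' @param prescription list with `total_gy` and `per_fraction_gy`.
#' @return an `oof_plan`.
#' @export
treatment_plan <- function(technique = c("3DCRT", "IMRT"), fields,
                           mlc_sequences = list(),
                           prescription = list(total_gy = 54,
                                               per_fraction_gy = 1.8)) {
  technique <- match.arg(technique)
  stopifnot(all(.PLAN_COLUMNS %in% names(fields)))
  fields$field_id <- as.character(fields$field_id)
  .validate_fields(fields)
  if (technique == "IMRT" && length(mlc_sequences)) {
    # a bare (sequence-less) IMRT table may be parsed, but a plan that
    # carries sequences must carry one per field; a bare plan fails at
    # job expansion instead
    miss <- setdiff(fields$field_id, names(mlc_sequences))
    if (length(miss))
      stop("IMRT plan missing MLC sequence(s) for field(s): ",
           paste(miss, collapse = ", "))
  }
  fr <- prescription$total_gy / prescription$per_fraction_gy
  if (abs(fr - round(fr)) > 1e-9)
    stop("prescription total must be an integer number of fractions")
  structure(list(technique = technique, fields = fields,
                 mlc_sequences = mlc_sequences, prescription = prescription),
            class = "oof_plan")
}

#' @export
print.oof_plan <- function(x, ...) {
  cat(sprintf("<oof_plan> %s, %d fields, %.0f MU total, %g Gy in %g Gy fractions\n",
              x$technique, nrow(x$fields), sum(x$fields$mu),
              x$prescription$total_gy, x$prescription$per_fraction_gy))
  invisible(x)
}

#' Parse a delimited plan table
#'
#' The file is tab- or whitespace-delimited with a `# oofdose-plan v1` header
#' line, a `# technique=` line, and one row per beam field with the
#' documented columns.  Jaw consistency (`field_x = x1 + x2` within 0.05 cm)
#' is validated and violations name the offending row.
#'
#' @param file path.
#' @param mlc_sequences optional named list of parsed MLC sequences.
#' @return an `oof_plan`.
#' @export
parse_plan_table <- function(file, mlc_sequences = list()) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# *oofdose-plan v1", lines[1]))
    stop("not an oofdose plan table (missing '# oofdose-plan v1' header): ",
         file)
  tec_ln <- grep("^# *technique=", lines, value = TRUE)
  technique <- if (length(tec_ln)) sub("^# *technique=", "", tec_ln[1]) else "3DCRT"
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   stringsAsFactors = FALSE)
  missing <- setdiff(.PLAN_COLUMNS, names(df))
  if (length(missing))
    stop("plan table missing column(s): ", paste(missing, collapse = ", "))
  treatment_plan(technique, df[, .PLAN_COLUMNS], mlc_sequences)
}

#' Serialize a plan back to the delimited dialect
#' @param plan an `oof_plan`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_plan_table <- function(plan, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# oofdose-plan v1",
               paste0("# technique=", plan$technique)), con)
  write.table(plan$fields, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Parse a dynamic MLC log file
#'
#' Delimited-text dialect: header lines `# oofdose-mlclog v1`,
#' `# field_id=`, `# leaf_pairs=`, `# control_points=`, then one row per
#' control point: `index`, cumulative `mu_fraction`, 60 bank-A then 60 bank-B
#' leaf-tip positions (cm at the isocenter plane; for every pair the bank-A
#' tip must not pass the bank-B tip).  `mu_fraction` must be non-decreasing
#' and is renormalized to end at exactly 1.
#'
#' @param file path.
#' @return data.frame with `index`, `mu_fraction` and matrix columns
#'   `bank_a`, `bank_b` (n x 60).
#' @export
parse_mlc_log <- function(file) {
  lines <- readLines(file)
  if (!length(lines) || !grepl("^# *oofdose-mlclog v1", lines[1]))
    stop("not an oofdose MLC log: ", file)
  hdr <- function(key, default = NA) {
    ln <- grep(paste0("^# *", key, "="), lines, value = TRUE)
    if (!length(ln)) return(default)
    sub(paste0("^# *", key, "="), "", ln[1])
  }
  n_pairs <- as.integer(hdr("leaf_pairs", "60"))
  m <- as.matrix(read.table(text = lines[!grepl("^#", lines)]))
  if (ncol(m) != 2 + 2 * n_pairs)
    stop("MLC log row width ", ncol(m), " != ", 2 + 2 * n_pairs)
  ord <- order(m[, 1])
  m <- m[ord, , drop = FALSE]
  mu_fr <- m[, 2]
  if (any(diff(mu_fr) < -1e-12))
    stop("non-monotone cumulative MU fraction in MLC log: ", file)
  if (mu_fr[length(mu_fr)] <= 0) stop("MLC log ends at zero MU fraction")
  mu_fr <- mu_fr / mu_fr[length(mu_fr)]
  a <- m[, 2 + seq_len(n_pairs), drop = FALSE]
  b <- m[, 2 + n_pairs + seq_len(n_pairs), drop = FALSE]
  crossed <- which(a > b + 1e-9, arr.ind = TRUE)
  if (nrow(crossed))
    stop("crossed leaf pair ", crossed[1, 2], " at control point index ",
         m[crossed[1, 1], 1])
  out <- data.frame(index = as.integer(m[, 1]), mu_fraction = mu_fr)
  out$bank_a <- a
  out$bank_b <- b
  expected <- as.integer(hdr("control_points", nrow(out)))
  if (!is.na(expected) && expected != nrow(out))
    stop("MLC log declares ", expected, " control points but has ", nrow(out))
  out
}

#' Serialize a control-point sequence to the MLC log dialect
#' @param cps control-point data.frame (as from [parse_mlc_log()]).
#' @param field_id field identifier written to the header.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_mlc_log <- function(cps, field_id, file) {
  n_pairs <- ncol(cps$bank_a)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# oofdose-mlclog v1",
               paste0("# field_id=", field_id),
               paste0("# leaf_pairs=", n_pairs),
               paste0("# control_points=", nrow(cps))), con)
  m <- cbind(cps$index, cps$mu_fraction, cps$bank_a, cps$bank_b)
  write.table(format(m, digits = 6, trim = TRUE, scientific = FALSE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Subsample a dynamic sequence into equally weighted control points
#'
#' Selects 1-based indices `step, 2*step, ...` up to the sequence length
#' (e.g. 5, 10, ..., 100 for a 100-point log at the default step of 5) and
#' assigns each selected point an equal share of the field's monitor units.
#'
#' @param cps control-point data.frame.
#' @param step positive integer subsampling stride.
#' @param field_mu monitor units of the field, split equally over the
#'   selected points (column `mu_weight`).
#' @return subsetted control-point data.frame with an `mu_weight` column.
#' @export
subsample_control_points <- function(cps, step = 5L, field_mu = 1) {
  step <- as.integer(step)
  if (is.na(step) || step <= 0L) stop("step must be a positive integer")
  n <- nrow(cps)
  if (n < step) stop("sequence length ", n, " < step ", step)
  sel <- seq(step, n, by = step)
  out <- cps[sel, , drop = FALSE]
  out$mu_weight <- field_mu / length(sel)
  rownames(out) <- NULL
  out
}

#' Expand a plan into a simulation job list
#'
#' Static (3DCRT) plans yield one job per field carrying the full field MU;
#' dynamic (IMRT) plans yield one job per subsampled control point with equal
#' MU shares (7 fields x 100-point logs at step 5 gives 140 jobs).
#'
#' @param plan an `oof_plan`.
#' @param step subsampling stride for dynamic sequences.
#' @return data.frame with `field_id`, `cp_index` (NA for static jobs) and
#'   `mu`.
#' @export
plan_jobs <- function(plan, step = 5L) {
  if (plan$technique == "3DCRT") {
    return(data.frame(field_id = plan$fields$field_id, cp_index = NA_integer_,
                      mu = plan$fields$mu, stringsAsFactors = FALSE))
  }
  jobs <- lapply(seq_len(nrow(plan$fields)), function(i) {
    fid <- plan$fields$field_id[i]
    seqi <- plan$mlc_sequences[[fid]]
    if (is.null(seqi)) stop("missing MLC sequence for IMRT field ", fid)
    sub <- subsample_control_points(seqi, step, plan$fields$mu[i])
    data.frame(field_id = fid, cp_index = sub$index, mu = sub$mu_weight,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, jobs)
}

#' Beam aperture at the isocenter plane
#'
#' Composes the jaw rectangle with (optionally) the per-pair MLC leaf gaps of
#' one control point.  The open region is the jaw rectangle intersected with
#' the union of per-pair gaps; with no control point (static field, leaves
#' retracted) the open region is the jaw rectangle itself.
#'
#' @param field one row of a plan's `fields` table (list or 1-row data.frame).
#' @param cp optional single control point: list with `bank_a`, `bank_b`
#'   numeric vectors of leaf-tip positions (cm).
#' @param mlc leaf geometry from [mlc_geometry()].
#' @return an `oof_aperture`: list with `jaw = c(x_lo, x_hi, y_lo, y_hi)` and
#'   `strips` (data.frame `y_lo, y_hi, x_lo, x_hi` of open gaps clipped to
#'   the jaws); `strips = NULL` means jaw-defined opening.
#' @export
aperture_at <- function(field, cp = NULL, mlc = mlc_geometry()) {
  jaw <- c(-field$x1, field$x2, -field$y1, field$y2)
  if (is.null(cp)) {
    return(structure(list(jaw = jaw, strips = NULL), class = "oof_aperture"))
  }
  a <- as.numeric(cp$bank_a)
  b <- as.numeric(cp$bank_b)
  keep <- mlc$y_hi > jaw[3] & mlc$y_lo < jaw[4]
  strips <- data.frame(
    y_lo = pmax(mlc$y_lo[keep], jaw[3]),
    y_hi = pmin(mlc$y_hi[keep], jaw[4]),
    x_lo = pmax(a[keep], jaw[1]),
    x_hi = pmin(b[keep], jaw[2])
  )
  strips <- strips[strips$x_hi > strips$x_lo, , drop = FALSE]
  rownames(strips) <- NULL
  structure(list(jaw = jaw, strips = strips), class = "oof_aperture")
}

#' Open area of an aperture, cm^2 at the isocenter plane
#' @param aperture an `oof_aperture`.
#' @return area in cm^2.
#' @export
aperture_area <- function(aperture) {
  j <- aperture$jaw
  if (is.null(aperture$strips))
    return((j[2] - j[1]) * (j[4] - j[3]))
  with(aperture$strips, sum((x_hi - x_lo) * (y_hi - y_lo)))
}
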