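# Thermoluminescent dosimeter (TLD) reduction chain: raw reader signal ->
# air kerma via the element and reader correction factors -> tissue dose via
# the 6 MeV mass energy-absorption coefficient ratio -> organ means with a
# quadrature uncertainty budget.

#' Build a table of TLD records
#'
#' @param dosimeter_id character ids.
#' @param organ organ names (keys of [organ_conversion_table()]).
#' @param technique `"3DCRT"` or `"IMRT"`.
#' @param rd raw readings, reader units (>= 0).
#' @param ecc element correction coefficients (> 0).
#' @param f_q reader-stability correction factors (> 0).
#' @param f_fad fading corrections (default 1: readout followed reset closely
#'   enough that fading is neglected).
#' @param f_e energy-dependence corrections (> 0).
#' @param f_alpha angular-dependence corrections (default 1: these dosimeters
#'   have no angular dependence above their energy threshold).
#' @param rcf reader calibration factors, reader units per mGy (> 0).
#' @return data.frame of class `oof_tld_records`.
#' @export
tld_records <- function(dosimeter_id, organ, technique, rd, ecc = 1,
                        f_q = 1, f_fad = 1, f_e = 1, f_alpha = 1, rcf = 1) {
  df <- data.frame(dosimeter_id = as.character(dosimeter_id),
                   organ = as.character(organ),
                   technique = as.character(technique),
                   rd = rd, ecc = ecc, f_q = f_q, f_fad = f_fad, f_e = f_e,
                   f_alpha = f_alpha, rcf = rcf, stringsAsFactors = FALSE)
  if (any(df$rd < 0)) stop("raw readings must be >= 0")
  if (any(df$rcf <= 0)) stop("reader calibration factor must be > 0")
  if (any(df$ecc <= 0 | df$f_q <= 0 | df$f_fad <= 0 | df$f_e <= 0 |
          df$f_alpha <= 0))
    stop("correction factors must be > 0")
  class(df) <- c("oof_tld_records", "data.frame")
  df
}

#' Read / write TLD record tables (delimited text)
#' @param file path.
#' @return an `oof_tld_records` data.frame.
#' @export
read_tld_table <- function(file) {
  df <- read.table(file, header = TRUE, stringsAsFactors = FALSE,
                   comment.char = "#")
  do.call(tld_records, df)
}

#' @rdname read_tld_table
#' @param records an `oof_tld_records` table.
#' @return `file`, invisibly.
#' @export
write_tld_table <- function(records, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# oofdose-tld v1", con)
  write.table(records, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Air kerma from a TLD reading
#'
#' K_air = RD x Ecc x f(Q) x f(fad) x f(E) x f(alpha) / RCF: the raw reading
#' is multiplied by the element correction coefficient and the reader
#' stability, fading, energy and angular correction factors, and divided by
#' the reader calibration factor.
#'
#' @param records an `oof_tld_records` table (or any data.frame with the
#'   chain's columns).
#' @return numeric vector of air kerma, mGy.
#' @export
kerma_from_reading <- function(records) {
  if (any(records$rcf == 0)) stop("reader calibration factor is zero")
  with(records, rd * ecc * f_q * f_fad * f_e * f_alpha / rcf)
}

#' Tissue dose from air kerma
#'
#' D_tissue = K_air x (muen/rho)_tissue / (muen/rho)_air with both
#' coefficients taken at the 6 MeV conversion energy, assuming electronic
#' equilibrium at the measurement point.
#'
#' @param k_air air kerma, mGy.
#' @param organ organ name(s), matched against `coefficients$organ`.
#' @param coefficients per-organ coefficient table, default
#'   [organ_conversion_table()].
#' @param air_muen_rho air mass energy-absorption coefficient at the
#'   conversion energy; default is the packaged air table at 6 MeV.
#' @return tissue dose, mGy.
#' @export
tissue_dose <- function(k_air, organ,
                        coefficients = organ_conversion_table(),
                        air_muen_rho = coefficient_at(get_material("air"),
                                                      6, "muen")) {
  idx <- match(organ, coefficients$organ)
  if (anyNA(idx))
    stop("no conversion coefficient for organ(s): ",
         paste(unique(organ[is.na(idx)]), collapse = ", "))
  k_air * coefficients$muen_rho[idx] / air_muen_rho
}

#' Uncertainty budget
#'
#' @param components data.frame with `name`, `rel_pct` (standard uncertainty,
#'   percent, already standardized, i.e. rectangular components stored as
#'   a/sqrt(3)) and `distribution` (`"normal"` or `"rectangular"`, a
#'   documentation tag).
#' @return an `oof_budget`.
#' @export
uncertainty_budget <- function(components = default_budget_components()) {
  stopifnot(all(c("name", "rel_pct", "distribution") %in% names(components)))
  if (any(components$rel_pct < 0)) stop("component uncertainties must be >= 0")
  structure(list(components = components), class = "oof_budget")
}

#' Default measurement uncertainty components
#'
#' Element correction coefficient 3.0% (normal), reader stability 3.8%
#' (normal), reader calibration factor 15.0% (normal) and energy dependence
#' 1.4% (rectangular, already divided by sqrt(3)).
#'
#' @return data.frame of components.
#' @export
default_budget_components <- function() {
  data.frame(
    name = c("element_correction", "reader_stability",
             "reader_calibration", "energy_dependence"),
    rel_pct = c(3.0, 3.8, 15.0, 1.4),
    distribution = c("normal", "normal", "normal", "rectangular"),
    stringsAsFactors = FALSE
  )
}

#' Combine an uncertainty budget in quadrature
#'
#' Law of propagation of uncertainty for independent multiplicative factors:
#' the square root of the sum of squared component standard uncertainties
#' (k = 1).
#'
#' @param budget an `oof_budget` or a numeric vector of component relative
#'   uncertainties in percent.
#' @return combined relative uncertainty, percent (k = 1).
#' @export
combine_uncertainty <- function(budget) {
  u <- if (inherits(budget, "oof_budget")) budget$components$rel_pct
       else as.numeric(budget)
  if (!length(u)) stop("empty uncertainty budget")
  sqrt(sum(u^2))
}

#' Reduce TLD records to an organ mean dose
#'
#' Averages the per-dosimeter tissue doses for one organ and technique.  The
#' reported SD is mean x the combined relative uncertainty of the budget
#' quoted at reporting precision (0.1 percentage point) - the convention of
#' the reference measurement campaign, whose printed SD column equals that
#' product for every organ.
#'
#' @param records TLD records for a single organ and technique.
#' @param budget an `oof_budget`.
#' @param coefficients organ conversion table.
#' @return one-row data.frame: `organ`, `technique`, `mean_mGy`, `sd_mGy`,
#'   `n`.
#' @export
organ_mean <- function(records, budget = uncertainty_budget(),
                       coefficients = organ_conversion_table()) {
  if (nrow(records) < 1L) stop("no records")
  if (length(unique(records$organ)) != 1L)
    stop("mixed organs in input: ",
         paste(unique(records$organ), collapse = ", "))
  if (length(unique(records$technique)) != 1L)
    stop("mixed techniques in input")
  d <- tissue_dose(kerma_from_reading(records), records$organ, coefficients)
  u <- round(combine_uncertainty(budget), 1) / 100
  data.frame(organ = records$organ[1], technique = records$technique[1],
             mean_mGy = mean(d), sd_mGy = mean(d) * u, n = nrow(records),
             stringsAsFactors = FALSE)
}

#' Reduce a full TLD table to per-organ dose measurements
#'
#' @param records an `oof_tld_records` table (any mix of organs/techniques).
#' @param budget an `oof_budget`.
#' @param coefficients organ conversion table.
#' @return data.frame with one row per organ x technique, ordered as the
#'   conversion table.
#' @export
reduce_tld <- function(records, budget = uncertainty_budget(),
                       coefficients = organ_conversion_table()) {
  groups <- split(records, list(records$technique, records$organ),
                  drop = TRUE)
  out <- do.call(rbind, lapply(groups, organ_mean, budget = budget,
                               coefficients = coefficients))
  ord <- order(match(out$technique, c("3DCRT", "IMRT")),
               match(out$organ, coefficients$organ))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
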