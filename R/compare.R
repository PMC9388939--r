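# Comparison statistics between dose sources (measurement, Monte Carlo,
# imported planning-system tables) and between delivery techniques.

utils::globalVariables(c("distance_cm", "dose_mGy", "source"))

#' Relative difference between a calculation and a measurement
#'
#' |calculation - measurement| / measurement x 100, in percent.  The
#' measurement is the denominator (gold standard).
#'
#' @param calculation calculated dose(s), mGy.
#' @param measurement measured dose(s), mGy; must be > 0.
#' @return relative difference(s), percent.
#' @export
relative_difference <- function(calculation, measurement) {
  if (any(measurement <= 0))
    stop("measurement must be > 0 (it is the comparison denominator)")
  abs(calculation - measurement) / measurement * 100
}

#' Per-organ comparison of two dose tables
#'
#' Builds the comparison report between two same-organ dose sets: per-organ
#' relative difference (with `b` as the reference) and ratio `a / b`, plus
#' arithmetic-mean aggregates.  Both the per-organ values and the aggregates
#' are always reported so the averaging convention is auditable.
#'
#' @param doses_a,doses_b data.frames with `organ` and a dose column
#'   (`dose_mGy` or `mean_mGy`).
#' @param label_a,label_b names of the two sources.
#' @return an `oof_comparison`: data.frame with per-organ rows; attributes
#'   `mean_rel_diff_pct`, `mean_ratio`, `labels`.
#' @export
compare_doses <- function(doses_a, doses_b, label_a = "a", label_b = "b") {
  get_dose <- function(df) {
    col <- intersect(c("dose_mGy", "mean_mGy"), names(df))[1]
    if (is.na(col)) stop("no dose column (dose_mGy or mean_mGy) in input")
    setNames(df[[col]], df$organ)
  }
  da <- get_dose(doses_a)
  db <- get_dose(doses_b)
  extra_a <- setdiff(names(da), names(db))
  extra_b <- setdiff(names(db), names(da))
  if (length(extra_a) || length(extra_b))
    stop("organ mismatch between the two tables; only in ", label_a, ": [",
         paste(extra_a, collapse = ", "), "], only in ", label_b, ": [",
         paste(extra_b, collapse = ", "), "]")
  db <- db[names(da)]
  out <- data.frame(organ = names(da),
                    dose_a_mGy = as.numeric(da),
                    dose_b_mGy = as.numeric(db),
                    rel_diff_pct = relative_difference(as.numeric(da),
                                                       as.numeric(db)),
                    ratio = as.numeric(da) / as.numeric(db),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mean_rel_diff_pct") <- mean(out$rel_diff_pct)
  attr(out, "mean_ratio") <- mean(out$ratio)
  attr(out, "labels") <- c(label_a, label_b)
  class(out) <- c("oof_comparison", "data.frame")
  out
}

#' Technique dose-ratio table (IMRT vs 3DCRT)
#'
#' Per-organ ratio IMRT / 3DCRT and the arithmetic mean of the per-organ
#' ratios.  A convenience wrapper around [compare_doses()].
#'
#' @param doses_imrt,doses_3dcrt per-organ dose tables.
#' @return an `oof_comparison` with the ratio column being IMRT / 3DCRT.
#' @export
technique_ratio_table <- function(doses_imrt, doses_3dcrt) {
  compare_doses(doses_imrt, doses_3dcrt, "IMRT", "3DCRT")
}

#' @export
print.oof_comparison <- function(x, ...) {
  lb <- attr(x, "labels")
  cat(sprintf("<oof_comparison> %s vs %s\n", lb[1], lb[2]))
  print.data.frame(x, digits = 4)
  cat(sprintf("mean relative difference: %.1f%%   mean ratio: %.2f\n",
              attr(x, "mean_rel_diff_pct"), attr(x, "mean_ratio")))
  invisible(x)
}

#' Dose versus distance from the target center
#'
#' Joins a per-organ dose table with target-to-organ center distances from a
#' phantom and sorts by distance (ties keep input order).
#'
#' @param report per-organ dose table (`organ` plus `dose_mGy` or
#'   `mean_mGy`).
#' @param phantom an `oof_phantom` containing the organs and a `ptv` label.
#' @param target target label name, default `"ptv"`.
#' @return data.frame with `organ`, `distance_cm`, `dose_mGy`, sorted by
#'   distance.
#' @export
dose_vs_distance <- function(report, phantom, target = "ptv") {
  col <- intersect(c("dose_mGy", "mean_mGy"), names(report))[1]
  if (is.na(col)) stop("no dose column in report")
  d <- vapply(report$organ, function(o) organ_distance(phantom, target, o),
              numeric(1))
  out <- data.frame(organ = report$organ, distance_cm = as.numeric(d),
                    dose_mGy = report[[col]], stringsAsFactors = FALSE)
  out <- out[order(out$distance_cm), , drop = FALSE]   # stable sort: ties
  rownames(out) <- NULL                                # keep input order
  out
}

#' Serialize / parse a comparison report
#'
#' Plain-text round trip of an `oof_comparison`, preserving the per-organ
#' table, labels and aggregates.
#'
#' @param comparison an `oof_comparison`.
#' @param file output path.
#' @return `file` invisibly / the re-read `oof_comparison`.
#' @export
write_comparison <- function(comparison, file) {
  con <- file(file, "w")
  on.exit(close(con))
  lb <- attr(comparison, "labels")
  writeLines(c("# oofdose-comparison v1",
               paste0("# labels=", lb[1], ",", lb[2])), con)
  write.table(comparison, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(file) {
  lines <- readLines(file)
  if (!grepl("^# *oofdose-comparison v1", lines[1]))
    stop("not an oofdose comparison report")
  lb <- strsplit(sub("^# *labels=", "", lines[2]), ",")[[1]]
  df <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                   stringsAsFactors = FALSE)
  attr(df, "mean_rel_diff_pct") <- mean(df$rel_diff_pct)
  attr(df, "mean_ratio") <- mean(df$ratio)
  attr(df, "labels") <- lb
  class(df) <- c("oof_comparison", "data.frame")
  df
}

#' Plot dose against distance on a log dose axis
#'
#' @param tables named list of dose-vs-distance tables from
#'   [dose_vs_distance()].
#' @return a ggplot object (requires the ggplot2 package).
#' @export
plot_dose_distance <- function(tables) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- do.call(rbind, lapply(names(tables), function(nm) {
    cbind(tables[[nm]], source = nm)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = distance_cm, y = dose_mGy,
                                   colour = source)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from target center (cm)",
                  y = "organ dose (mGy)")
}
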