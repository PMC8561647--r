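#' Metric configuration
#'
#' @param field_threshold fraction of the field's own current maximum that
#'   defines the suprathreshold hot spot (0.7, 0.8 or 0.9 in the study
#'   design; any value in (0,1) is accepted).
#' @param n_avg_nodes observation nodes averaged per target field value
#'   (4 by default, 10 as the alternative).
#' @param peak_percentile percentile defining the field-peak node set.
#' @param df_cond fixed conductivity-uncertainty defocalization factor.
#' @return object of class `metric_config`.
#' @export
metric_config <- function(field_threshold = 0.8, n_avg_nodes = 4L,
                          peak_percentile = 0.99, df_cond = 1.05) {
  stopifnot(field_threshold > 0, field_threshold < 1, n_avg_nodes >= 1)
  structure(list(field_threshold = field_threshold,
                 n_avg_nodes = as.integer(n_avg_nodes),
                 peak_percentile = peak_percentile, df_cond = df_cond),
            class = "metric_config")
}

#' Average absolute deviation (AAD) of the suprathreshold field from target
#'
#' The cost function of the inverse problem: the mean Euclidean distance
#' from the target of all observation nodes whose field magnitude is at or
#' above `threshold` times the field's own current maximum. It can be read
#' as the effective radius of the focal hot spot.
#'
#' @param field a `field_map` on the observation surface.
#' @param target 3-vector, mm.
#' @param threshold fraction in (0,1) of the known field maximum.
#' @return AAD in mm.
#' @export
aad <- function(field, target, threshold = 0.8) {
  mx <- max(field$magnitude)
  if (!is.finite(mx) || mx <= 0) stop("aad: field is all-zero; threshold undefined")
  sel <- field$magnitude >= threshold * mx
  d <- sqrt(rowSums((field$points[sel, , drop = FALSE] -
                       matrix(target, sum(sel), 3, byrow = TRUE))^2))
  mean(d)
}

target_field_value <- function(field, point, n_avg_nodes) {
  d <- sqrt(rowSums((field$points - matrix(point, nrow(field$points), 3,
                                           byrow = TRUE))^2))
  mean(field$magnitude[order(d)[seq_len(min(n_avg_nodes, length(d)))]])
}

#' Average relative differentiation (ARD) between neighbour targets
#'
#' The somatotopy metric `1 - mean_n(|E_Tn| / |E_T|)`: zero when the
#' neighbour-target fields equal the target field, one (100%) when they
#' vanish. Every field value is the mean magnitude over the `n_avg_nodes`
#' observation nodes nearest to the point in question.
#'
#' @param field a `field_map`.
#' @param target_set a `target_set` with at least one neighbour.
#' @param n_avg_nodes nodes averaged per field value.
#' @return ARD as a fraction.
#' @export
ard <- function(field, target_set, n_avg_nodes = 4L) {
  if (is.null(target_set$neighbors) || nrow(target_set$neighbors) == 0)
    stop("ard: target has no neighbours")
  et <- target_field_value(field, target_set$target, n_avg_nodes)
  if (et <= 0) stop("ard: zero field at the target")
  en <- apply(target_set$neighbors, 1, function(p)
    target_field_value(field, p, n_avg_nodes))
  1 - mean(en / et)
}

#' Field loss at the target after optimization
#'
#' `100 * (mean_n |E_before| / mean_n |E_after| - 1)` over the
#' `n_avg_nodes` observation nodes nearest to the target, where `before`
#' is the sulcus-aligned pose and `after` the inverse-problem solution.
#' Negative values indicate a field gain.
#'
#' @param field_before,field_after `field_map`s on the same observation
#'   surface.
#' @param target 3-vector, mm.
#' @param n_avg_nodes nodes averaged.
#' @return field loss in percent.
#' @export
field_loss <- function(field_before, field_after, target, n_avg_nodes = 4L) {
  eb <- target_field_value(field_before, target, n_avg_nodes)
  ea <- target_field_value(field_after, target, n_avg_nodes)
  if (ea <= 0) stop("field_loss: zero field at the target after optimization")
  100 * (eb / ea - 1)
}

#' Distance from target to the field-peak centroid
#'
#' The peak position is the unweighted centroid of all nodes whose
#' magnitude is at or above the given percentile of the magnitude
#' distribution.
#'
#' @param field a `field_map`.
#' @param target 3-vector, mm.
#' @param percentile fraction (0.99 by default).
#' @return distance in mm.
#' @export
peak_deviation <- function(field, target, percentile = 0.99) {
  thr <- stats::quantile(field$magnitude, percentile, names = FALSE)
  sel <- field$magnitude >= thr
  ctr <- colMeans(field$points[sel, , drop = FALSE])
  sqrt(sum((ctr - target)^2))
}

#' Defocalization-corrected focality improvement
#'
#' `1 - (DF_final * AAD_final) / (DF_initial * AAD_initial)`: zero when the
#' corrected final cost equals the corrected initial cost, approaching one
#' when the corrected final cost vanishes.
#'
#' @param report an `ip_report` (or any list with `aad_initial`,
#'   `aad_final`, `df_initial`, `df_final`).
#' @return improvement as a fraction.
#' @export
focality_improvement <- function(report) {
  den <- report$df_initial * report$aad_initial
  if (!is.finite(den) || den == 0)
    stop("focality_improvement: zero or invalid initial cost")
  1 - (report$df_final * report$aad_final) / den
}

#' Summarize a batch of inverse-problem reports
#'
#' Mean and sample standard deviation per metric, the two-sided
#' paired-sample t-test p-value for the final-vs-initial ARD, and the
#' per-run map values `DF_cond * DF_coil * AAD` used for absolute-size
#' visualization.
#'
#' @param reports list of `ip_report` objects.
#' @param df_cond conductivity-uncertainty defocalization factor.
#' @return list with elements `summary` (data frame of mean/STD per
#'   metric), `p_value_ard` (NA when fewer than 2 reports or ARD is
#'   degenerate), and `map_values` (data frame with initial/final values).
#' @export
summarize_batch <- function(reports, df_cond = 1.05) {
  num <- function(f) vapply(reports, function(r) {
    v <- r[[f]]
    if (is.null(v) || !is.finite(v)) NA_real_ else v
  }, 1)
  fields <- c("aad_initial", "aad_final", "df_initial", "df_final",
              "ard_initial", "ard_final", "field_loss",
              "peak_dev_initial", "peak_dev_final", "improvement")
  tab <- data.frame(metric = fields,
                    mean = vapply(fields, function(f) mean(num(f), na.rm = TRUE), 1),
                    sd = vapply(fields, function(f) stats::sd(num(f), na.rm = TRUE), 1),
                    row.names = NULL)
  p <- NA_real_
  ai <- num("ard_initial"); af <- num("ard_final")
  ok <- is.finite(ai) & is.finite(af)
  if (sum(ok) >= 2) {
    p <- if (stats::sd(af[ok] - ai[ok]) == 0) 1
    else stats::t.test(af[ok], ai[ok], paired = TRUE)$p.value
  }
  mv <- data.frame(run = seq_along(reports),
                   map_initial = df_cond * num("df_initial") * num("aad_initial"),
                   map_final = df_cond * num("df_final") * num("aad_final"))
  list(summary = tab, p_value_ard = p, map_values = mv)
}
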