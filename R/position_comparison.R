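# Pairing of sitting/supine measurements, CIEDE2000 comparison, and the
# cohort-level acceptability summary.

#' A per-position region-color measurement
#'
#' @param patient_id Identifier.
#' @param position `"sitting"` or `"supine"`.
#' @param region_colors Named list mapping region labels to `(L, a, b)`
#'   triples; must contain at least `"edge"`.
#' @return A `"position_measurement"` object.
#' @export
position_measurement <- function(patient_id, position = c("sitting", "supine"),
                                 region_colors) {
  position <- match.arg(position)
  if (!"edge" %in% names(region_colors))
    stop("region_colors must contain at least the edge region", call. = FALSE)
  structure(list(patient_id = patient_id, position = position,
                 region_colors = lapply(region_colors, function(x)
                   .as_color_matrix(x, "region color"))),
            class = "position_measurement")
}

#' Acceptability / perceptibility thresholds
#'
#' The 50:50% acceptability threshold (AT) is the color difference at which
#' half of observers accept the difference; AT = 4.1, common in gingival
#' color studies, is the default (4.0 and 2.8 are reported alternatives).
#' The 50:50% perceptibility threshold (PT) has no established default for
#' tongue color and is optional.
#'
#' @param AT Acceptability threshold, positive.
#' @param PT Optional perceptibility threshold, positive and `<= AT`.
#' @return A `"threshold_set"` list.
#' @export
threshold_set <- function(AT = 4.1, PT = NULL) {
  if (AT <= 0) stop("AT must be positive", call. = FALSE)
  if (!is.null(PT)) {
    if (PT <= 0) stop("PT must be positive", call. = FALSE)
    if (PT > AT) stop("PT must not exceed AT", call. = FALSE)
  }
  structure(list(AT = AT, PT = PT), class = "threshold_set")
}

#' Compare the sitting and supine measurements of one patient
#'
#' Computes the CIEDE2000 difference with the sitting color as reference
#' and the supine color as sample, so the signed components
#' \eqn{\Delta L', \Delta C', \Delta H'} read supine minus sitting.
#'
#' @param sitting,supine `"position_measurement"` objects sharing a
#'   `patient_id`, with positions `"sitting"` and `"supine"` respectively.
#' @param region Region to compare (default `"edge"`).
#' @param k Parametric coefficients, see [ciede2000()].
#' @return A `"ciede2000"` result with the `patient_id` attached.
#' @export
compare_positions <- function(sitting, supine, region = "edge",
                              k = c(kL = 1, kC = 1, kH = 1)) {
  stopifnot(inherits(sitting, "position_measurement"),
            inherits(supine, "position_measurement"))
  if (!identical(sitting$patient_id, supine$patient_id))
    stop("pairing error: measurements belong to different patients (",
         sitting$patient_id, " vs ", supine$patient_id, ")", call. = FALSE)
  if (sitting$position != "sitting" || supine$position != "supine")
    stop("pairing error: expected one sitting and one supine measurement",
         call. = FALSE)
  for (m in list(sitting, supine))
    if (!region %in% names(m$region_colors))
      stop("region '", region, "' missing from ", m$position, " measurement",
           call. = FALSE)
  res <- ciede2000(sitting$region_colors[[region]],
                   supine$region_colors[[region]], k = k)
  res$patient_id <- sitting$patient_id
  res$region <- region
  res
}

#' Classify a color difference against the acceptability threshold
#'
#' Acceptable means strictly `dE00 < AT`: a difference exactly at the
#' threshold is classified unacceptable.
#'
#' @param result A `"ciede2000"` result (or a bare dE00 number).
#' @param thresholds A [threshold_set()].
#' @return `TRUE` if acceptable.
#' @export
classify_acceptability <- function(result, thresholds = threshold_set()) {
  stopifnot(inherits(thresholds, "threshold_set"))
  dE <- if (inherits(result, "ciede2000")) result$dE00 else as.numeric(result)
  dE < thresholds$AT
}

#' Build a patient comparison record
#'
#' @param result A `"ciede2000"` result carrying a `patient_id`.
#' @param thresholds A [threshold_set()].
#' @return A `"patient_comparison"` list: `patient_id`, `result`,
#'   `acceptable`, `threshold_used`.
#' @export
patient_comparison <- function(result, thresholds = threshold_set()) {
  structure(list(patient_id = result$patient_id, result = result,
                 acceptable = classify_acceptability(result, thresholds),
                 threshold_used = thresholds$AT),
            class = "patient_comparison")
}

#' Summarize a cohort of patient comparisons
#'
#' @param comparisons Non-empty list of `"patient_comparison"` objects.
#' @return A `"cohort_summary"`: `n`, `mean_dE00`, `median_dE00` (even-n
#'   median is the mean of the two central order statistics),
#'   `proportion_acceptable`, and a per-patient data.frame.
#' @export
summarize_cohort <- function(comparisons) {
  if (length(comparisons) == 0L)
    stop("cannot summarize an empty cohort", call. = FALSE)
  per <- do.call(rbind, lapply(comparisons, function(p)
    data.frame(patient_id = p$patient_id,
               dE00 = p$result$dE00,
               dL_prime = p$result$dL_prime,
               dC_prime = p$result$dC_prime,
               dH_prime = p$result$dH_prime,
               acceptable = p$acceptable,
               threshold_used = p$threshold_used)))
  structure(list(
    n = nrow(per),
    mean_dE00 = mean(per$dE00),
    median_dE00 = stats::median(per$dE00),
    proportion_acceptable = mean(per$acceptable),
    per_patient = per), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients\n", x$n))
  cat(sprintf("  mean dE00   = %.2f\n", x$mean_dE00))
  cat(sprintf("  median dE00 = %.2f\n", x$median_dE00))
  cat(sprintf("  acceptable (dE00 < %.1f): %d/%d (%.1f%%)\n",
              x$per_patient$threshold_used[1L],
              sum(x$per_patient$acceptable), x$n,
              100 * x$proportion_acceptable))
  invisible(x)
}

#' Position comparison for a whole table of L*a*b* pairs
#'
#' Convenience wrapper running [compare_positions()] over a wide-format
#' data.frame of paired edge colors (as returned by
#' [read_lab_pairs_csv()] or [tongue_cohort_lab()]) and assembling the
#' per-patient comparison table.
#'
#' @param pairs Data.frame with columns `patient_id`, `L_sit`, `a_sit`,
#'   `b_sit`, `L_sup`, `a_sup`, `b_sup`.
#' @param thresholds A [threshold_set()].
#' @param k Parametric coefficients, see [ciede2000()].
#' @return A data.frame mirroring the cohort comparison table: the input
#'   columns plus `dL_prime`, `dC_prime`, `dH_prime`, `dE00`, `acceptable`.
#' @export
compare_lab_table <- function(pairs, thresholds = threshold_set(),
                              k = c(kL = 1, kC = 1, kH = 1)) {
  need <- c("patient_id", "L_sit", "a_sit", "b_sit", "L_sup", "a_sup", "b_sup")
  if (!all(need %in% names(pairs)))
    stop("pairs must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  comparisons <- lapply(seq_len(nrow(pairs)), function(i) {
    sit <- position_measurement(pairs$patient_id[i], "sitting",
      list(edge = c(pairs$L_sit[i], pairs$a_sit[i], pairs$b_sit[i])))
    sup <- position_measurement(pairs$patient_id[i], "supine",
      list(edge = c(pairs$L_sup[i], pairs$a_sup[i], pairs$b_sup[i])))
    patient_comparison(compare_positions(sit, sup, k = k), thresholds)
  })
  summ <- summarize_cohort(comparisons)
  out <- merge(pairs[need], summ$per_patient, by = "patient_id", sort = FALSE)
  attr(out, "cohort_summary") <- summ
  out
}
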