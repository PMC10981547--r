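# Association of dE00 with patient covariates (Pearson r for numeric items,
# correlation ratio eta^2 for categorical ones) and flagging of laboratory
# values above the diagnostic reference criteria.

#' Pearson correlation between a covariate and dE00
#'
#' Pairwise deletion of missing values, then the sample Pearson correlation
#' via [stats::cor.test()]; the two-sided p-value comes from the t transform
#' with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (NAs deleted pairwise).
#' @param name Covariate name carried into the result.
#' @return An `"association_result"` list: `name`, `statistic`
#'   (`"pearson_r"`), `value`, `p_value`, `n_used`.
#' @export
pearson_r <- function(x, y, name = deparse(substitute(x))) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(name = name, statistic = "pearson_r",
                 value = unname(ct$estimate), p_value = ct$p.value,
                 n_used = n),
            class = "association_result")
}

#' Correlation ratio (eta squared) between a grouping and dE00
#'
#' \eqn{\eta^2} is the between-group sum of squares divided by the total sum
#' of squares; the p-value is the one-way ANOVA F test from [stats::aov()].
#'
#' @param values Numeric outcome vector.
#' @param groups Categorical grouping of the same length.
#' @param name Covariate name carried into the result.
#' @return An `"association_result"` with `statistic = "eta_squared"`.
#' @export
eta_squared <- function(values, groups, name = deparse(substitute(groups))) {
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  groups <- droplevels(groups)
  n <- length(values)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  if (nlevels(groups) < 2L)
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (stats::var(values) == 0)
    stop("undefined correlation ratio: zero total variance", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  ss_between <- tab["groups", "Sum Sq"]
  ss_total <- sum(tab[, "Sum Sq"])
  structure(list(name = name, statistic = "eta_squared",
                 value = ss_between / ss_total,
                 p_value = tab["groups", "Pr(>F)"], n_used = n),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.3f (p = %.3f, n = %d)\n",
              x$name, if (x$statistic == "pearson_r") "r" else "eta^2",
              x$value, x$p_value, x$n_used))
  invisible(x)
}

#' Associate dE00 with every biometric covariate
#'
#' Runs [pearson_r()] for the numeric covariates (age, BMI, SBP, DBP, TG,
#' HDL-C, LDL-C, HbA1c, FPG) and [eta_squared()] for the categorical ones
#' (sex, smoking, CVD drug), mirroring the cohort association table.
#'
#' @param dE00 Numeric vector of per-patient color differences, aligned to
#'   `biometrics` by `patient_id` order.
#' @param biometrics Data.frame as from [read_biometrics_csv()].
#' @return Data.frame with columns `item`, `statistic`, `value`, `p_value`,
#'   `n_used`.
#' @export
associate_covariates <- function(dE00, biometrics) {
  if (length(dE00) != nrow(biometrics))
    stop("dE00 and biometrics must have the same length", call. = FALSE)
  numeric_items <- c(age = "age", bmi = "bmi", sbp = "sbp", dbp = "dbp",
                     tg = "tg", hdl_c = "hdl_c", ldl_c = "ldl_c",
                     hba1c = "hba1c", fpg = "fpg")
  cat_items <- c(sex = "sex", smoking = "smoking", cvd_drug = "cvd_drug")
  rows <- list()
  for (item in names(cat_items))
    if (item %in% names(biometrics))
      rows[[item]] <- eta_squared(dE00, biometrics[[item]], name = item)
  for (item in names(numeric_items))
    if (item %in% names(biometrics))
      rows[[item]] <- pearson_r(biometrics[[item]], dE00, name = item)
  do.call(rbind, lapply(rows, function(r)
    data.frame(item = r$name, statistic = r$statistic, value = r$value,
               p_value = r$p_value, n_used = r$n_used,
               row.names = NULL)))
}

#' Default diagnostic reference criteria
#'
#' Prompt-consultation cutoffs for lifestyle-related disease: grade II/III
#' blood pressure (SBP >= 160 mmHg or DBP >= 100 mmHg, counting as a single
#' item), triglycerides >= 500 mg/dL, fasting plasma glucose >= 126 mg/dL,
#' HbA1c >= 6.5%, and LDL-C >= 180 mg/dL (high-risk dyslipidemia
#' consultation level). HDL-C >= 100 mg/dL can be added as an optional item.
#'
#' @param include_hdl Add the optional HDL-C >= 100 item?
#' @return Named list of predicate functions over a one-row biometric
#'   record; class `"reference_criteria"`.
#' @export
reference_criteria <- function(include_hdl = FALSE) {
  ge <- function(field, cutoff) {
    force(field); force(cutoff)
    function(rec) {
      v <- rec[[field]]
      !is.null(v) && !is.na(v) && v >= cutoff
    }
  }
  crit <- list(
    blood_pressure = function(rec) {
      sbp <- rec[["sbp"]]; dbp <- rec[["dbp"]]
      (!is.null(sbp) && !is.na(sbp) && sbp >= 160) ||
        (!is.null(dbp) && !is.na(dbp) && dbp >= 100)
    },
    tg = ge("tg", 500),
    fpg = ge("fpg", 126),
    hba1c = ge("hba1c", 6.5),
    ldl_c = ge("ldl_c", 180)
  )
  if (include_hdl) crit$hdl_c <- ge("hdl_c", 100)
  structure(crit, class = "reference_criteria")
}

#' Items of a biometric record above the reference criteria
#'
#' @param record A one-row data.frame or named list of biometric values.
#' @param criteria A [reference_criteria()] set (non-empty). Missing fields
#'   simply cannot satisfy their items.
#' @return Character vector of satisfied item names (blood pressure counts
#'   once even if both SBP and DBP exceed their cutoffs).
#' @export
flag_above_reference <- function(record, criteria = reference_criteria()) {
  if (length(criteria) == 0L) stop("criteria must be non-empty", call. = FALSE)
  if (is.data.frame(record)) record <- as.list(record[1L, ])
  hits <- vapply(criteria, function(f) isTRUE(f(record)), logical(1))
  names(criteria)[hits]
}

#' Flag counts for a whole biometric table
#'
#' @param biometrics Data.frame of biometric records.
#' @param criteria A [reference_criteria()] set.
#' @return Data.frame `patient_id`, `items` (comma-separated), `n_items`.
#' @export
flag_table <- function(biometrics, criteria = reference_criteria()) {
  rows <- lapply(seq_len(nrow(biometrics)), function(i) {
    items <- flag_above_reference(biometrics[i, ], criteria)
    data.frame(patient_id = biometrics$patient_id[i],
               items = paste(items, collapse = ","),
               n_items = length(items))
  })
  do.call(rbind, rows)
}

#' Flag counts split by acceptability group
#'
#' Cross-tabulates patients by acceptability of their positional color
#' difference against how many laboratory items exceed the reference
#' criteria, reporting per group the count and percentage with at most one
#' flagged item and with two or more.
#'
#' @param comparison Data.frame with `patient_id` and `acceptable` columns
#'   (e.g. [compare_lab_table()] output or `summarize_cohort()$per_patient`).
#' @param flags Data.frame with `patient_id` and `n_items`
#'   ([flag_table()] output); every compared patient must appear.
#' @return Data.frame, one row per group (`acceptable`, `unacceptable`):
#'   `n`, `n_le1`, `pct_le1`, `n_ge2`, `pct_ge2` (percentages `NA` for an
#'   empty group).
#' @export
count_flags_by_group <- function(comparison, flags) {
  m <- merge(comparison[, c("patient_id", "acceptable")],
             flags[, c("patient_id", "n_items")], by = "patient_id")
  if (nrow(m) < nrow(comparison))
    stop("every compared patient needs a flag count", call. = FALSE)
  one_group <- function(sel) {
    n <- sum(sel)
    n_le1 <- sum(m$n_items[sel] <= 1L)
    n_ge2 <- sum(m$n_items[sel] >= 2L)
    data.frame(n = n, n_le1 = n_le1,
               pct_le1 = if (n > 0) 100 * n_le1 / n else NA_real_,
               n_ge2 = n_ge2,
               pct_ge2 = if (n > 0) 100 * n_ge2 / n else NA_real_)
  }
  cbind(group = c("acceptable", "unacceptable"),
        rbind(one_group(m$acceptable), one_group(!m$acceptable)))
}
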