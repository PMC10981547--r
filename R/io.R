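# CSV readers for the biometric and paired-Lab tables, run configuration
# with lossless JSON round-tripping, and accessors for the bundled data.

# normalize a header: lower-case, drop unit suffixes like "(mmHg)", map
# punctuation/space runs to "_"
.norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("\\(.*\\)", "", x)
  x <- gsub("[^a-z0-9]+", "_", x)
  x <- gsub("^_+|_+$", "", x)
  aliases <- c(no = "patient_id", id = "patient_id", patient = "patient_id",
               patient_no = "patient_id",
               hdl = "hdl_c", ldl = "ldl_c", cvd = "cvd_drug")
  ifelse(x %in% names(aliases), aliases[x], x)
}

# the paper-world tables print minus as U+2212; normalize before parsing
.norm_minus <- function(x) gsub("−", "-", x)

.parse_numeric_col <- function(x, col, file) {
  x <- .norm_minus(trimws(as.character(x)))
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("unparseable numeric value '%s' in column '%s', row %d of %s",
                 x[bad[1L]], col, bad[1L], file), call. = FALSE)
  out
}

#' Read a biometric table from CSV
#'
#' Headers are matched case-insensitively with unit suffixes (e.g.
#' `"SBP (mmHg)"`) stripped. Blank cells become missing values; unknown
#' columns are kept with a warning; unparseable numeric cells are row-level
#' errors.
#'
#' @param path CSV path.
#' @return Data.frame with columns `patient_id`, `age`, `sex`, `bmi`,
#'   `smoking`, `cvd_drug`, `sbp`, `dbp`, `tg`, `hdl_c`, `ldl_c`, `hba1c`,
#'   `fpg` (those present in the file).
#' @export
read_biometrics_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- .norm_header(names(raw))
  known_numeric <- c("age", "bmi", "sbp", "dbp", "tg", "hdl_c", "ldl_c",
                     "hba1c", "fpg")
  known <- c("patient_id", "sex", "smoking", "cvd_drug", known_numeric)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("unknown biometric column(s): ", paste(unknown, collapse = ", "))
  for (col in intersect(known_numeric, names(raw)))
    raw[[col]] <- .parse_numeric_col(raw[[col]], col, basename(path))
  for (col in intersect(c("sex", "smoking", "cvd_drug"), names(raw))) {
    v <- trimws(raw[[col]])
    v[v == ""] <- NA
    raw[[col]] <- v
  }
  raw
}

#' Read paired sitting/supine L*a*b* colors from CSV
#'
#' Accepts either the wide layout (one row per patient with columns
#' `L_sit, a_sit, b_sit, L_sup, a_sup, b_sup`) or a long layout with a
#' `position` column (`sitting` / `supine`) and `L, a, b` columns, one row
#' per measurement. In the long layout a duplicate patient/position row or
#' a patient missing one position is an error.
#'
#' @param path CSV path.
#' @return Wide-format data.frame, one row per patient.
#' @export
read_lab_pairs_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  names(raw) <- .norm_header(names(raw))
  file <- basename(path)
  if ("position" %in% names(raw)) {
    need <- c("patient_id", "position", "l", "a", "b")
    if (!all(need %in% names(raw)))
      stop("long layout needs columns patient_id, position, L, a, b",
           call. = FALSE)
    raw$position <- tolower(trimws(raw$position))
    key <- paste(raw$patient_id, raw$position)
    if (anyDuplicated(key))
      stop("duplicate patient/position row: ", key[duplicated(key)][1L],
           call. = FALSE)
    for (col in c("l", "a", "b"))
      raw[[col]] <- .parse_numeric_col(raw[[col]], col, file)
    ids <- unique(raw$patient_id)
    rows <- lapply(ids, function(id) {
      sit <- raw[raw$patient_id == id & raw$position == "sitting", ]
      sup <- raw[raw$patient_id == id & raw$position == "supine", ]
      if (nrow(sit) != 1L || nrow(sup) != 1L)
        stop("unpaired row: patient ", id, " lacks a sitting or supine entry",
             call. = FALSE)
      data.frame(patient_id = id,
                 L_sit = sit$l, a_sit = sit$a, b_sit = sit$b,
                 L_sup = sup$l, a_sup = sup$a, b_sup = sup$b)
    })
    return(do.call(rbind, rows))
  }
  need <- c("patient_id", "l_sit", "a_sit", "b_sit", "l_sup", "a_sup", "b_sup")
  if (!all(need %in% names(raw)))
    stop("wide layout needs columns patient_id, L_sit, a_sit, b_sit, ",
         "L_sup, a_sup, b_sup", call. = FALSE)
  if (anyDuplicated(raw$patient_id))
    stop("duplicate patient_id: ",
         raw$patient_id[duplicated(raw$patient_id)][1L], call. = FALSE)
  for (col in setdiff(names(raw), c("patient_id")))
    raw[[col]] <- .parse_numeric_col(raw[[col]], col, file)
  names(raw)[match(c("l_sit", "l_sup"), names(raw))] <- c("L_sit", "L_sup")
  if ("de00" %in% names(raw)) names(raw)[names(raw) == "de00"] <- "dE00"
  if ("dl_prime" %in% names(raw)) names(raw)[names(raw) == "dl_prime"] <- "dL_prime"
  if ("dc_prime" %in% names(raw)) names(raw)[names(raw) == "dc_prime"] <- "dC_prime"
  if ("dh_prime" %in% names(raw)) names(raw)[names(raw) == "dh_prime"] <- "dH_prime"
  raw
}

#' Bundled 18-patient example cohort: paired edge L*a*b* colors
#'
#' Edge-region tongue colors of 18 Kampo outpatients measured in the
#' sitting and supine positions with a calibrated integrating-sphere
#' imaging rig, together with the signed CIEDE2000 components and dE00 as
#' originally reported (components computed from unrounded internal values,
#' so they can differ from a recomputation from the 1-decimal triples by up
#' to about 0.1).
#'
#' @return Data.frame, one row per patient.
#' @export
tongue_cohort_lab <- function() {
  read_lab_pairs_csv(system.file("extdata", "cohort_lab_pairs.csv",
                                 package = "tonguecolor", mustWork = TRUE))
}

#' Bundled 18-patient example cohort: biometrics
#'
#' Age, sex, BMI, smoking, cardiovascular medication, blood pressure and
#' laboratory values for the same cohort as [tongue_cohort_lab()].
#'
#' @return Data.frame, one row per patient.
#' @export
tongue_cohort_biometrics <- function() {
  read_biometrics_csv(system.file("extdata", "cohort_biometrics.csv",
                                  package = "tonguecolor", mustWork = TRUE))
}

#' CIEDE2000 implementation-verification pairs
#'
#' The 34 standard L*a*b* input pairs exercising the formula's hue-mean and
#' wraparound corner cases, with expected dE00 values cross-checked against
#' two independent implementations.
#'
#' @return Data.frame with columns `L1,a1,b1,L2,a2,b2,dE00`.
#' @export
ciede2000_reference_pairs <- function() {
  utils::read.csv(system.file("extdata", "ciede2000_verification_pairs.csv",
                              package = "tonguecolor", mustWork = TRUE))
}

#' Run configuration
#'
#' All tunables of a pipeline run in one object that serializes losslessly
#' to a single JSON document, so every reported number is traceable to its
#' configuration.
#'
#' @param white_point `"D65"` or `"D50"`.
#' @param ratios A [partition_ratios()].
#' @param thresholds A [threshold_set()].
#' @param k Parametric coefficients `c(kL =, kC =, kH =)`.
#' @param include_hdl Include the optional HDL-C reference item?
#' @param seed Integer seed for any stochastic step.
#' @return A `"run_config"` list.
#' @export
run_config <- function(white_point = "D65", ratios = partition_ratios(),
                       thresholds = threshold_set(),
                       k = c(kL = 1, kC = 1, kH = 1),
                       include_hdl = FALSE, seed = 1L) {
  structure(list(white_point = white_point,
                 ratios = unclass(ratios)[c("edge", "posterior", "apex")],
                 thresholds = list(AT = thresholds$AT, PT = thresholds$PT),
                 k = as.list(.check_k(k)),
                 include_hdl = include_hdl,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `"run_config"`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(white_point = x$white_point,
             ratios = do.call(partition_ratios,
                              lapply(as.list(x$ratios), as.numeric)),
             thresholds = threshold_set(AT = as.numeric(x$thresholds$AT),
                                        PT = if (!is.null(x$thresholds$PT))
                                          as.numeric(x$thresholds$PT)),
             k = as.numeric(unlist(x$k)), include_hdl = x$include_hdl,
             seed = x$seed)
}

#' Write a Table-2-style comparison CSV
#' @param comparison Output of [compare_lab_table()].
#' @param path CSV path.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE)
  invisible(path)
}
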