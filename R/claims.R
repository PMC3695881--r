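#' Canonical claims columns
#'
#' One row of a visit table describes a single claim a physician (or the
#' hospital) lodges for one visit to a hospitalised patient.
#' @noRd
CLAIM_COLUMNS <- c(
  "hospital_id", "patient_id", "physician_id", "admission_id",
  "service_date", "claim_category", "benefit_amount", "patient_age",
  "procedure_code"
)

CLAIM_CATEGORIES <- c("ancillary", "medical", "hospital")

#' Column mapping for a claims file
#'
#' Maps the canonical claim fields onto the column names used by a
#' particular delimited file.  The default is the identity mapping.  A
#' mapping can also be stored as a YAML or JSON file with one
#' `canonical: actual` entry per field and loaded by passing the file path
#' to [read_claims()].
#'
#' @param ... Named character entries overriding individual mappings,
#'   e.g. `physician_id = "provider_no"`.
#'
#' @return A named character vector of length 9 (class `claims_schema`);
#'   names are the canonical fields, values the file column names.
#' @examples
#' claims_schema(physician_id = "provider_no")
#' @export
claims_schema <- function(...) {
  schema <- stats::setNames(CLAIM_COLUMNS, CLAIM_COLUMNS)
  override <- c(...)
  if (length(override)) {
    bad <- setdiff(names(override), CLAIM_COLUMNS)
    if (length(bad)) {
      stop("unknown claim fields in schema: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    schema[names(override)] <- override
  }
  structure(schema, class = "claims_schema")
}

load_schema <- function(schema) {
  if (inherits(schema, "claims_schema")) return(schema)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    mapping <- yaml::read_yaml(schema)
    return(do.call(claims_schema, mapping))
  }
  if (is.character(schema) || is.list(schema)) {
    return(do.call(claims_schema, as.list(schema)))
  }
  stop("`schema` must be a claims_schema, a named mapping, or a file path",
       call. = FALSE)
}

#' Read and validate a claims file
#'
#' Reads a delimited text file of physician-visit claims, renames columns
#' to the canonical schema, validates each row and returns a visit table.
#' Rows failing validation are dropped; the rejected rows together with a
#' per-row reason are kept in the `rejections` attribute so that no record
#' disappears silently.
#'
#' Validation rules: all identifier fields non-empty; `service_date`
#' parseable as a date (ISO `YYYY-MM-DD`); `claim_category` one of
#' `ancillary`, `medical`, `hospital`; `benefit_amount` a non-negative
#' number; `patient_age` a non-negative number.
#'
#' @param path Path to a CSV/TSV file with a header row (delimiter is
#'   sniffed from the extension: `.tsv` reads as tab-separated).
#' @param schema A [claims_schema()], a named mapping, or the path of a
#'   YAML/JSON mapping file.
#'
#' @return A tibble of validated claims (class `visit_table`) with
#'   attributes `rejections` (tibble of `row`, `reason`) and `provenance`
#'   (the source path).
#' @seealso [filter_hospitals()], [build_pcn()], [compute_outcomes()]
#' @export
read_claims <- function(path, schema = claims_schema()) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  schema <- load_schema(schema)
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  mapped <- as.character(unclass(schema))
  missing <- setdiff(mapped, names(raw))
  if (length(missing)) {
    stop("claims file is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- raw[mapped]
  names(raw) <- names(schema)
  validate_claims(raw, provenance = path)
}

#' Validate an in-memory claims table
#'
#' Applies the same row-level validation as [read_claims()] to a data
#' frame already in the canonical schema.
#'
#' @param claims Data frame with the canonical claim columns.
#' @param provenance Source description stored on the result.
#' @return A `visit_table` tibble; invalid rows are moved to the
#'   `rejections` attribute with a reason.
#' @export
validate_claims <- function(claims, provenance = "in-memory") {
  claims <- tibble::as_tibble(claims)
  missing <- setdiff(CLAIM_COLUMNS, names(claims))
  if (length(missing)) {
    stop("claims table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  claims <- claims[CLAIM_COLUMNS]
  n <- nrow(claims)

  dates <- claims$service_date
  if (!inherits(dates, "Date")) {
    dates <- as.Date(as.character(claims$service_date),
                     format = "%Y-%m-%d", optional = TRUE)
  }
  amount <- suppressWarnings(as.numeric(claims$benefit_amount))
  age <- suppressWarnings(as.numeric(claims$patient_age))
  category <- as.character(claims$claim_category)

  id_ok <- function(x) !is.na(x) & nzchar(trimws(as.character(x)))
  reason <- character(n)
  flag <- function(bad, why) {
    bad <- bad & !nzchar(reason)
    reason[bad] <<- why
  }
  flag(!id_ok(claims$hospital_id), "empty hospital_id")
  flag(!id_ok(claims$patient_id), "empty patient_id")
  flag(!id_ok(claims$physician_id), "empty physician_id")
  flag(!id_ok(claims$admission_id), "empty admission_id")
  flag(is.na(dates), "unparseable service_date")
  flag(is.na(category) | !category %in% CLAIM_CATEGORIES,
       "claim_category not one of ancillary/medical/hospital")
  flag(is.na(amount), "unparseable benefit_amount")
  flag(!is.na(amount) & amount < 0, "negative benefit_amount")
  flag(is.na(age), "unparseable patient_age")
  flag(!is.na(age) & age < 0, "negative patient_age")

  keep <- !nzchar(reason)
  out <- claims[keep, ]
  out$service_date <- dates[keep]
  out$benefit_amount <- amount[keep]
  out$patient_age <- age[keep]
  out$claim_category <- category[keep]

  rejections <- tibble::tibble(
    row = which(!keep),
    reason = reason[!keep]
  )
  if (nrow(rejections)) {
    warning(nrow(rejections), " claim row(s) rejected during validation",
            call. = FALSE)
  }
  # admission episodes must belong to a single hospital stay of one patient
  key <- paste(out$hospital_id, out$patient_id, sep = "\r")
  split_adm <- tapply(key, out$admission_id, function(k) length(unique(k)))
  if (any(split_adm > 1)) {
    stop("admission_id mapped to more than one (hospital, patient) pair: ",
         paste(head(names(split_adm)[split_adm > 1], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(out,
            rejections = rejections,
            provenance = provenance,
            class = c("visit_table", class(out)))
}

#' Restrict a visit table to eligible hospitals
#'
#' Keeps only hospitals in which at least `min_patients` distinct patients
#' carry the index procedure code, and restricts the retained hospitals'
#' records to those patients (the cohort the outcome measures are defined
#' on).  The study design this mirrors admits hospitals with at least five
#' index-procedure patients.
#'
#' @param visits A `visit_table` from [read_claims()] or
#'   [validate_claims()].
#' @param min_patients Minimum number of distinct matching patients
#'   (default 5).
#' @param procedure_code Code identifying the index procedure
#'   (default `"THR"`, total hip replacement).
#'
#' @return A filtered `visit_table`; a warning is issued when no hospital
#'   qualifies.
#' @export
filter_hospitals <- function(visits, min_patients = 5,
                             procedure_code = "THR") {
  stopifnot(min_patients >= 1)
  match_rows <- visits$procedure_code == procedure_code
  eligible_pat <- unique(visits[match_rows, c("hospital_id", "patient_id")])
  counts <- table(eligible_pat$hospital_id)
  keep_hosp <- names(counts)[counts >= min_patients]
  if (!length(keep_hosp)) {
    warning("no hospital has >= ", min_patients,
            " patients with procedure code '", procedure_code, "'",
            call. = FALSE)
  }
  keep_pat <- eligible_pat[eligible_pat$hospital_id %in% keep_hosp, ]
  key <- paste(visits$hospital_id, visits$patient_id, sep = "\r")
  keep_key <- paste(keep_pat$hospital_id, keep_pat$patient_id, sep = "\r")
  out <- visits[key %in% keep_key, ]
  structure(out,
            rejections = attr(visits, "rejections"),
            provenance = attr(visits, "provenance"),
            class = class(visits))
}

#' Hospital outcome measures
#'
#' Computes, for one hospital, the outcome vector the network indices are
#' related to: mean hospitalisation cost per patient (all claim categories
#' contribute, as the insurer pays all of them), the readmission rate --
#' the percentage of patients with more than one distinct admission
#' episode -- and the unweighted mean patient age (one age per patient,
#' taken from the patient's earliest record; conflicting ages are resolved
#' to that value with a warning).
#'
#' The readmission rate is
#' \deqn{100 \times \frac{\#\{\text{patients with} > 1\ \text{admission}\}}
#'   {\#\{\text{patients}\}}}
#'
#' @param visits A `visit_table`.
#' @param hospital_id Hospital to summarise; must occur in `visits`.
#'
#' @return A one-row tibble: `hospital_id`, `mean_cost_per_patient`,
#'   `readmission_rate` (percent in \[0, 100\]), `mean_patient_age`,
#'   `n_patients`.
#' @export
compute_outcomes <- function(visits, hospital_id) {
  rows <- visits[visits$hospital_id == hospital_id, ]
  if (!nrow(rows)) {
    stop("unknown hospital_id: ", hospital_id, call. = FALSE)
  }
  n_patients <- length(unique(rows$patient_id))
  total_cost <- sum(rows$benefit_amount)

  adm <- tapply(rows$admission_id, rows$patient_id,
                function(a) length(unique(a)))
  readmission_rate <- 100 * sum(adm > 1) / n_patients

  ord <- rows[order(rows$service_date), ]
  first_age <- tapply(ord$patient_age, ord$patient_id, function(a) a[[1]])
  n_ages <- tapply(rows$patient_age, rows$patient_id,
                   function(a) length(unique(a)))
  if (any(n_ages > 1)) {
    warning("conflicting patient ages in hospital ", hospital_id,
            "; using the age on the earliest record", call. = FALSE)
  }
  tibble::tibble(
    hospital_id = hospital_id,
    mean_cost_per_patient = total_cost / n_patients,
    readmission_rate = readmission_rate,
    mean_patient_age = mean(first_age),
    n_patients = n_patients
  )
}

#' Outcome measures for every hospital
#'
#' @param visits A `visit_table`.
#' @return A tibble with one [compute_outcomes()] row per hospital,
#'   ordered by `hospital_id`.
#' @export
compute_all_outcomes <- function(visits) {
  ids <- sort(unique(visits$hospital_id))
  dplyr::bind_rows(lapply(ids, function(h) compute_outcomes(visits, h)))
}
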