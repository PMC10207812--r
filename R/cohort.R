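#' Truncate raw ICD-10 codes to three-character categories
#'
#' Strips dots and whitespace, uppercases, and keeps the first three
#' characters, the category level at which IHD (I20--I25) and HF (I50) are
#' identified.
#'
#' @param code Character vector of raw ICD-10 codes (e.g. `"I25.103"`).
#' @return Character vector of three-character category codes.
#' @export
#' @examples
#' truncate_icd(c("I25.103", "I50.9", "e11"))
truncate_icd <- function(code) {
  if (!length(code)) return(character())
  x <- toupper(gsub("[.[:space:]]", "", as.character(code)))
  bad <- is.na(x) | nchar(x) < 3L
  if (any(bad))
    stop(sprintf("parse error: ICD code shorter than 3 alphanumeric characters: %s",
                 paste(unique(code[bad]), collapse = ", ")))
  substr(x, 1L, 3L)
}

#' Ischemic heart disease / heart failure code predicates
#'
#' IHD is the ICD-10 block I20--I25; HF is category I50.
#'
#' @param code Character vector of three-character category codes.
#' @return Logical vector.
#' @export
is_ihd <- function(code) code %in% ihd_codes()

#' @rdname is_ihd
#' @export
is_hf <- function(code) code == "I50"

split_diagnoses <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

#' Clean raw admission rows
#'
#' Applies the record-level hygiene rules: rows with missing patient id,
#' sex, age, admission index or diagnoses are dropped (`missing`); rows with
#' unparseable ages/indices/sex or ICD codes shorter than three characters
#' are dropped (`invalid`); diagnosis codes are truncated to categories and
#' duplicate codes within an admission collapsed to one occurrence;
#' byte-identical (patient, admission, diagnosis-set) rows are deduplicated
#' (`redundant`).
#'
#' @param rows Data frame with columns `patient_id`, `sex`, `age`,
#'   `admission_index`, `diagnoses` (semicolon-separated codes).
#' @return List with `records` (cleaned data frame, diagnoses normalised)
#'   and `dropped` (named counts per reason).
#' @export
clean_records <- function(rows) {
  req <- c("patient_id", "sex", "age", "admission_index", "diagnoses")
  miss_col <- setdiff(req, names(rows))
  if (length(miss_col))
    stop(sprintf("input is missing column(s): %s", paste(miss_col, collapse = ", ")))
  rows <- rows[, req, drop = FALSE]
  dropped <- c(missing = 0L, invalid = 0L, redundant = 0L)

  blank <- function(v) is.na(v) | trimws(as.character(v)) == ""
  is_missing <- blank(rows$patient_id) | blank(rows$sex) | blank(rows$age) |
    blank(rows$admission_index) | blank(rows$diagnoses)
  dropped["missing"] <- sum(is_missing)
  rows <- rows[!is_missing, , drop = FALSE]

  sex <- tolower(trimws(as.character(rows$sex)))
  sex[sex %in% c("m", "male")] <- "male"
  sex[sex %in% c("f", "female")] <- "female"
  age <- suppressWarnings(as.numeric(rows$age))
  idx <- suppressWarnings(as.integer(rows$admission_index))
  diag_ok <- vapply(split_diagnoses(rows$diagnoses), function(d) {
    d <- trimws(d)
    d <- d[d != ""]
    length(d) > 0L && all(nchar(gsub("[.[:space:]]", "", d)) >= 3L)
  }, logical(1))
  ok <- sex %in% c("male", "female") & !is.na(age) & age >= 0 & age <= 120 &
    !is.na(idx) & idx >= 0 & diag_ok
  dropped["invalid"] <- sum(!ok)
  rows <- rows[ok, , drop = FALSE]
  sex <- sex[ok]; age <- age[ok]; idx <- idx[ok]

  diagnoses <- vapply(split_diagnoses(rows$diagnoses), function(d) {
    d <- trimws(d)
    paste(unique(truncate_icd(d[d != ""])), collapse = ";")
  }, character(1))

  out <- data.frame(patient_id = as.character(rows$patient_id),
                    sex = sex, age = age, admission_index = idx,
                    diagnoses = diagnoses, stringsAsFactors = FALSE)
  dup <- duplicated(out[, c("patient_id", "admission_index", "diagnoses")])
  dropped["redundant"] <- sum(dup)
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, dropped = dropped)
}

#' Assemble per-patient histories from cleaned admission records
#'
#' Groups cleaned records by patient, orders admissions by
#' `admission_index`, and records sex and the age at the first included
#' admission. Patients with conflicting sex across rows, or with the same
#' admission index carrying different diagnosis sets, are dropped as
#' inconsistent.
#'
#' @param records Cleaned records (the `records` element of
#'   [clean_records()]).
#' @return List with `histories` (list of `patient_history` objects:
#'   `patient_id`, `sex`, `age`, `admissions` as a list of code vectors,
#'   `indices`) and `dropped_inconsistent` (count of dropped patients).
#' @export
build_histories <- function(records) {
  if (!nrow(records))
    return(list(histories = list(), dropped_inconsistent = 0L))
  sp <- split(records, records$patient_id)
  dropped <- 0L
  histories <- vector("list", length(sp))
  keep <- logical(length(sp))
  for (i in seq_along(sp)) {
    r <- sp[[i]]
    r <- r[order(r$admission_index), , drop = FALSE]
    if (length(unique(r$sex)) > 1L || anyDuplicated(r$admission_index)) {
      dropped <- dropped + 1L
      next
    }
    histories[[i]] <- structure(
      list(patient_id = r$patient_id[1L],
           sex = r$sex[1L],
           age = r$age[1L],
           admissions = split_diagnoses(r$diagnoses),
           indices = r$admission_index),
      class = "patient_history")
    keep[i] <- TRUE
  }
  list(histories = histories[keep], dropped_inconsistent = dropped)
}

#' @export
print.patient_history <- function(x, ...) {
  cat(sprintf("Patient %s (%s, age %g): %d admissions\n",
              x$patient_id, x$sex, x$age, length(x$admissions)))
  for (i in seq_along(x$admissions))
    cat(sprintf("  [%d] %s\n", x$indices[i], paste(x$admissions[[i]], collapse = " ")))
  invisible(x)
}

first_index_where <- function(history, pred) {
  hit <- vapply(history$admissions, function(a) any(pred(a)), logical(1))
  if (any(hit)) history$indices[which(hit)[1L]] else NA_integer_
}

#' Assign patients to case / control / excluded cohorts
#'
#' Applies the cohort rules in order: (1) patients with no IHD code are
#' excluded (`no_ihd`); (2) patients whose first HF admission is not
#' strictly after their first IHD admission -- HF first, or HF and IHD
#' co-diagnosed on the same admission -- are excluded
#' (`hf_before_or_with_ihd`); (3) patients with fewer than three total
#' admissions are excluded (`fewer_than_three_admissions`). Remaining
#' patients are cases if HF ever occurs (necessarily after IHD), controls
#' otherwise. Indices are reported in the input's own `admission_index`
#' space.
#'
#' @param histories List of `patient_history` objects.
#' @return Data frame with columns `patient_id`, `group`,
#'   `exclusion_reason`, `first_ihd_index`, `first_hf_index`.
#' @export
assign_cohorts <- function(histories) {
  n <- length(histories)
  out <- data.frame(patient_id = character(n), group = character(n),
                    exclusion_reason = character(n),
                    first_ihd_index = NA_integer_, first_hf_index = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    h <- histories[[i]]
    ihd <- first_index_where(h, is_ihd)
    hf <- first_index_where(h, is_hf)
    out$patient_id[i] <- h$patient_id
    out$first_ihd_index[i] <- ihd
    out$first_hf_index[i] <- hf
    if (is.na(ihd)) {
      out$group[i] <- "excluded"; out$exclusion_reason[i] <- "no_ihd"
    } else if (!is.na(hf) && hf <= ihd) {
      out$group[i] <- "excluded"; out$exclusion_reason[i] <- "hf_before_or_with_ihd"
    } else if (length(h$admissions) < 3L) {
      out$group[i] <- "excluded"; out$exclusion_reason[i] <- "fewer_than_three_admissions"
    } else if (!is.na(hf)) {
      out$group[i] <- "case"; out$exclusion_reason[i] <- "none"
    } else {
      out$group[i] <- "control"; out$exclusion_reason[i] <- "none"
    }
  }
  out
}

#' Censor a case history at the first heart-failure admission
#'
#' Truncates a case patient's history to the admissions strictly before the
#' first HF admission, so that model features reflect only pre-outcome
#' information (no label leakage through the HF admission itself).
#'
#' @param history A `patient_history`.
#' @param assignment The matching row of [assign_cohorts()] output.
#' @return The truncated `patient_history`.
#' @export
censor_case_history <- function(history, assignment) {
  if (!identical(assignment$group, "case"))
    stop(sprintf("censor_case_history() requires a case patient; %s is '%s'",
                 history$patient_id, assignment$group))
  keep <- history$indices < assignment$first_hf_index
  if (!any(keep))
    stop(sprintf("case %s has no admissions before first HF admission",
                 history$patient_id))
  history$admissions <- history$admissions[keep]
  history$indices <- history$indices[keep]
  history
}

#' Read/write admission records CSV
#'
#' One row per admission with columns `patient_id`, `sex`, `age`,
#' `admission_index`, `diagnoses` (semicolon-separated ordered ICD-10
#' codes).
#'
#' @param records Data frame of admission rows.
#' @param path File path.
#' @return `read_admissions()` returns the data frame; `write_admissions()`
#'   returns `path` invisibly.
#' @export
write_admissions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_admissions
#' @export
read_admissions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character", sex = "character",
                                 age = "numeric", admission_index = "integer",
                                 diagnoses = "character"))
}
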