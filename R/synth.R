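#' Default ICD-10 category vocabulary for synthetic cohorts
#'
#' Forty-five three-character ICD-10 categories: the ischemic heart disease
#' block I20--I25, heart failure I50, and a set of cardiovascular, metabolic,
#' renal and respiratory comorbidities commonly recorded on admissions of
#' elderly cardiac patients.
#'
#' @return Character vector of ICD-10 category codes.
#' @export
default_vocabulary <- function() {
  c("I20", "I21", "I22", "I23", "I24", "I25", "I50",
    "I10", "I11", "I48", "N18", "J44", "E11", "E78", "I63", "I67", "I70",
    "K21", "K29", "N39", "J18", "J96", "E14", "E87", "D64", "N40", "M81",
    "K76", "B18", "C34", "E04", "G45", "G20", "F32", "H25", "I49", "I34",
    "I38", "J42", "K80", "M17", "M54", "R07", "R42", "Z95")
}

#' Default per-admission code prevalences
#'
#' Probability that each vocabulary code appears on any single admission.
#' Heart failure (I50) is never sampled marginally: its placement is
#' structural (cases only, strictly after the first IHD admission).
#'
#' @return Named numeric vector of probabilities over [default_vocabulary()].
#' @export
default_prevalence <- function() {
  p <- c(I20 = 0.15, I21 = 0.08, I22 = 0.01, I23 = 0.01, I24 = 0.02,
         I25 = 0.30, I50 = 0.00,
         I10 = 0.40, I11 = 0.06, I48 = 0.10, N18 = 0.10, J44 = 0.08,
         E11 = 0.22, E78 = 0.25, I63 = 0.06, I67 = 0.05, I70 = 0.05,
         K21 = 0.05, K29 = 0.08, N39 = 0.04, J18 = 0.07, J96 = 0.03,
         E14 = 0.03, E87 = 0.04, D64 = 0.06, N40 = 0.04, M81 = 0.04,
         K76 = 0.03, B18 = 0.01, C34 = 0.01, E04 = 0.03, G45 = 0.03,
         G20 = 0.01, F32 = 0.02, H25 = 0.03, I49 = 0.04, I34 = 0.03,
         I38 = 0.01, J42 = 0.02, K80 = 0.03, M17 = 0.03, M54 = 0.06,
         R07 = 0.08, R42 = 0.03, Z95 = 0.02)
  p[default_vocabulary()]
}

#' Default case prevalence shifts
#'
#' Additive per-admission prevalence increments applied to case patients:
#' five heart-failure-associated comorbidities (atrial fibrillation I48,
#' chronic kidney disease N18, COPD J44, type 2 diabetes E11, hypertensive
#' heart disease I11) each shifted by +0.4.
#'
#' @return Named numeric vector of prevalence deltas.
#' @export
default_shift <- function() {
  c(I48 = 0.4, N18 = 0.4, J44 = 0.4, E11 = 0.4, I11 = 0.4)
}

#' Default disease-pair transition motifs
#'
#' Extra probability, in case patients only, that `to` appears in the
#' admission immediately following one containing `from`. The three default
#' motifs follow recognised progression pathways (diabetes to nephropathy,
#' hypertension to hypertensive heart disease, atrial fibrillation to
#' stroke).
#'
#' @return Data frame with columns `from`, `to`, `delta`.
#' @export
default_motifs <- function() {
  data.frame(from  = c("E11", "I10", "I48"),
             to    = c("N18", "I11", "I63"),
             delta = c(0.3, 0.3, 0.3),
             stringsAsFactors = FALSE)
}

ihd_codes <- function() sprintf("I2%d", 0:5)

#' Configuration for the synthetic admission-record generator
#'
#' Describes a synthetic hospital-discharge cohort: case patients progress
#' from ischemic heart disease (IHD, I20--I25) to heart failure (HF, I50);
#' control patients have IHD and never HF. Case/control differences are
#' planted two ways: marginal prevalence shifts (`case_prevalence_shift`)
#' and disease-pair transition motifs (`transition_motifs`), so that the
#' node/rank and edge network features can be probed independently.
#'
#' Codes are included on an admission independently with their configured
#' probability, so the diagnosis count per admission is Poisson-binomial
#' with mean equal to the summed prevalences (about 3 for controls, 5 for
#' cases under the defaults; a minimum of one code is enforced).
#'
#' @param n_case,n_control Number of case / control patients (>= 0).
#' @param disease_vocabulary ICD-10 category codes; must contain at least
#'   one of I20--I25, and I50.
#' @param base_prevalence Named probability vector over the vocabulary.
#' @param case_prevalence_shift Named vector of additive deltas applied to
#'   case patients. Probabilities are clipped to [0, 1] (with a warning),
#'   never renormalised.
#' @param transition_motifs Data frame `from`, `to`, `delta`: extra
#'   probability in cases that `to` appears in the admission following one
#'   containing `from`.
#' @param admissions_min,admissions_lambda Admissions per patient are
#'   `admissions_min + rpois(admissions_lambda)` (default min 1, mean 5).
#'   Cases receive one additional terminal admission carrying I50.
#' @param age_case,age_control Normal age distribution per group, as
#'   `c(mean =, sd =)`, truncated to [18, 100] years.
#' @param sex_ratio Probability that a patient is male.
#' @param seed Integer seed; identical configurations generate identical
#'   populations.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_case,
                         n_control,
                         disease_vocabulary = default_vocabulary(),
                         base_prevalence = default_prevalence(),
                         case_prevalence_shift = default_shift(),
                         transition_motifs = default_motifs(),
                         admissions_min = 1L,
                         admissions_lambda = 4,
                         age_case = c(mean = 74.28, sd = 9.55),
                         age_control = c(mean = 68.33, sd = 10.74),
                         sex_ratio = 0.48,
                         seed = 1L) {
  if (!is.numeric(n_case) || length(n_case) != 1L || is.na(n_case) || n_case < 0)
    stop("invalid configuration: 'n_case' must be a single nonnegative number")
  if (!is.numeric(n_control) || length(n_control) != 1L || is.na(n_control) || n_control < 0)
    stop("invalid configuration: 'n_control' must be a single nonnegative number")
  if (!any(ihd_codes() %in% disease_vocabulary))
    stop("invalid configuration: 'disease_vocabulary' must contain an I20-I25 code")
  if (!"I50" %in% disease_vocabulary)
    stop("invalid configuration: 'disease_vocabulary' must contain \"I50\"")
  if (is.null(names(base_prevalence)) ||
      !all(disease_vocabulary %in% names(base_prevalence)))
    stop("invalid configuration: 'base_prevalence' must name every vocabulary code")
  base_prevalence <- base_prevalence[disease_vocabulary]
  if (any(is.na(base_prevalence)) || any(base_prevalence < 0) || any(base_prevalence > 1))
    stop("invalid configuration: 'base_prevalence' values must lie in [0, 1]")
  if (length(case_prevalence_shift) &&
      (is.null(names(case_prevalence_shift)) ||
       !all(names(case_prevalence_shift) %in% disease_vocabulary)))
    stop("invalid configuration: 'case_prevalence_shift' names must be vocabulary codes")
  if (!is.data.frame(transition_motifs) ||
      !all(c("from", "to", "delta") %in% names(transition_motifs)))
    stop("invalid configuration: 'transition_motifs' needs columns from, to, delta")
  if (nrow(transition_motifs) &&
      (!all(transition_motifs$from %in% disease_vocabulary) ||
       !all(transition_motifs$to %in% disease_vocabulary)))
    stop("invalid configuration: 'transition_motifs' codes must be in the vocabulary")
  if (nrow(transition_motifs) &&
      (any(transition_motifs$delta < 0) || any(transition_motifs$delta > 1)))
    stop("invalid configuration: 'transition_motifs' deltas must lie in [0, 1]")
  if (admissions_min < 1)
    stop("invalid configuration: 'admissions_min' must be >= 1")
  if (admissions_lambda < 0)
    stop("invalid configuration: 'admissions_lambda' must be >= 0")
  for (nm in c("age_case", "age_control")) {
    v <- get(nm)
    if (!all(c("mean", "sd") %in% names(v)) || v[["sd"]] < 0)
      stop(sprintf("invalid configuration: '%s' must be c(mean =, sd >= 0)", nm))
  }
  if (sex_ratio < 0 || sex_ratio > 1)
    stop("invalid configuration: 'sex_ratio' must lie in [0, 1]")

  case_prev <- base_prevalence
  if (length(case_prevalence_shift)) {
    case_prev[names(case_prevalence_shift)] <-
      case_prev[names(case_prevalence_shift)] + case_prevalence_shift
    if (any(case_prev > 1) || any(case_prev < 0)) {
      warning("case prevalence shifts pushed probabilities outside [0, 1]; clipping")
      case_prev <- pmin(pmax(case_prev, 0), 1)
    }
  }

  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 disease_vocabulary = disease_vocabulary,
                 base_prevalence = base_prevalence,
                 case_prevalence_shift = case_prevalence_shift,
                 case_prevalence = case_prev,
                 transition_motifs = transition_motifs,
                 admissions_min = as.integer(admissions_min),
                 admissions_lambda = admissions_lambda,
                 age_case = age_case,
                 age_control = age_control,
                 sex_ratio = sex_ratio,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Sample one admission's diagnosis set for one patient.
# prev_codes: codes of the previous admission (motif triggers), or NULL.
sample_admission <- function(vocab, prev, prev_codes, motifs, is_case, force_ihd) {
  codes <- vocab[stats::runif(length(vocab)) < prev]
  if (is_case && !is.null(prev_codes) && nrow(motifs)) {
    for (i in seq_len(nrow(motifs))) {
      if (motifs$delta[i] > 0 &&
          motifs$from[i] %in% prev_codes &&
          !(motifs$to[i] %in% codes) &&
          stats::runif(1) < motifs$delta[i])
        codes <- c(codes, motifs$to[i])
    }
  }
  if (force_ihd && !any(ihd_codes() %in% codes)) {
    ihd <- intersect(ihd_codes(), vocab)
    w <- prev[match(ihd, vocab)]
    if (sum(w) <= 0) w <- rep(1, length(ihd))
    codes <- c(sample(ihd, 1L, prob = w), codes)
  }
  if (!length(codes)) {
    w <- prev
    if (sum(w) <= 0) w <- rep(1, length(vocab))
    codes <- sample(vocab, 1L, prob = w)
  }
  unique(codes)
}

#' Generate a synthetic hospital-discharge population
#'
#' Produces one row per admission: `patient_id`, `sex`, `age`,
#' `admission_index` (1-based temporal order) and `diagnoses` (ordered
#' semicolon-separated ICD-10 categories). Every patient has an IHD code on
#' the first admission. Case patients carry I50 on one terminal admission
#' appended after their core trajectory, so HF always occurs strictly after
#' the first IHD diagnosis; controls never carry I50.
#'
#' @param config A [synth_config()].
#' @return Data frame of admission records (class `data.frame`).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  vocab <- config$disease_vocabulary
  n_tot <- config$n_case + config$n_control
  if (n_tot == 0L)
    return(data.frame(patient_id = character(), sex = character(),
                      age = numeric(), admission_index = integer(),
                      diagnoses = character(), stringsAsFactors = FALSE))
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))
  out <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    is_case <- groups[i] == "case"
    pid <- sprintf("P%06d", i)
    sex <- if (stats::runif(1) < config$sex_ratio) "male" else "female"
    agep <- if (is_case) config$age_case else config$age_control
    age <- round(min(100, max(18, stats::rnorm(1, agep[["mean"]], agep[["sd"]]))))
    prev <- if (is_case) config$case_prevalence else config$base_prevalence
    prev["I50" == vocab] <- 0  # HF placement is structural, never marginal
    n_core <- config$admissions_min + stats::rpois(1, config$admissions_lambda)
    n_adm <- n_core + as.integer(is_case)
    adms <- vector("list", n_adm)
    prev_codes <- NULL
    for (t in seq_len(n_adm)) {
      codes <- sample_admission(vocab, prev, prev_codes,
                                config$transition_motifs, is_case,
                                force_ihd = (t == 1L))
      if (is_case && t == n_adm) codes <- unique(c(codes, "I50"))
      adms[[t]] <- codes
      prev_codes <- codes
    }
    out[[i]] <- data.frame(patient_id = pid, sex = sex, age = age,
                           admission_index = seq_len(n_adm),
                           diagnoses = vapply(adms, paste, "", collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a signal-free (null) population
#'
#' Identical to [generate_population()] except that all case prevalence
#' shifts and transition-motif deltas are forced to zero and both groups
#' draw ages from the control distribution, so that the case/control labels
#' carry no signal beyond the structural IHD/HF marker codes themselves.
#' Used as the negative control for the whole pipeline.
#'
#' @param config A [synth_config()].
#' @return Data frame of admission records.
#' @export
generate_null_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  null_cfg <- synth_config(
    n_case = config$n_case,
    n_control = config$n_control,
    disease_vocabulary = config$disease_vocabulary,
    base_prevalence = config$base_prevalence,
    case_prevalence_shift = numeric(0),
    transition_motifs = data.frame(from = character(), to = character(),
                                   delta = numeric(), stringsAsFactors = FALSE),
    admissions_min = config$admissions_min,
    admissions_lambda = config$admissions_lambda,
    age_case = config$age_control,
    age_control = config$age_control,
    sex_ratio = config$sex_ratio,
    seed = config$seed)
  generate_population(null_cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  patients: %d cases, %d controls\n", x$n_case, x$n_control))
  cat(sprintf("  vocabulary: %d ICD-10 categories\n", length(x$disease_vocabulary)))
  cat(sprintf("  shifted codes: %s\n",
              if (length(x$case_prevalence_shift))
                paste(names(x$case_prevalence_shift), collapse = ", ") else "none"))
  cat(sprintf("  transition motifs: %d\n", nrow(x$transition_motifs)))
  cat(sprintf("  admissions/patient: %d + Poisson(%g)\n",
              x$admissions_min, x$admissions_lambda))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
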