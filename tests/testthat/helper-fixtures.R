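mk_history <- function(adms, pid = "P") {
  structure(list(patient_id = pid, sex = "male", age = 70,
                 admissions = adms, indices = seq_along(adms)),
            class = "patient_history")
}

# Hand-labelled 12-patient cohort fixture covering every assignment branch:
# HF-first, same-admission co-diagnosis, <3 admissions, no IHD, cases with
# HF at different positions, controls, and rule-ordering collisions.
twelve_patient_fixture <- function() {
  mk <- function(pid, adms) {
    structure(list(patient_id = pid, sex = "male", age = 70,
                   admissions = adms, indices = seq_along(adms)),
              class = "patient_history")
  }
  histories <- list(
    mk("T01", list("I50", "I21", "I10")),
    mk("T02", list(c("I21", "I50"), "I10", "E11")),
    mk("T03", list("I21", "I10")),
    mk("T04", list("I21", "I10", "I50")),
    mk("T05", list("I25", "E11", "I10")),
    mk("T06", list("I10", "E11", "N18")),
    mk("T07", list("I20", "E11", "I10", c("I50", "E11"))),
    mk("T08", list("I10", "I22", "E78", "K21", "M54")),
    mk("T09", list("I50", "I21")),
    mk("T10", list("E11")),
    mk("T11", list("I24", "I50", "I10")),
    mk("T12", list("I21", c("I21", "I10"), "E78")))
  expected <- data.frame(
    patient_id = sprintf("T%02d", 1:12),
    group = c("excluded", "excluded", "excluded", "case", "control",
              "excluded", "case", "control", "excluded", "excluded",
              "case", "control"),
    exclusion_reason = c("hf_before_or_with_ihd", "hf_before_or_with_ihd",
                         "fewer_than_three_admissions", "none", "none",
                         "no_ihd", "none", "none", "hf_before_or_with_ihd",
                         "no_ihd", "none", "none"),
    first_ihd_index = c(2L, 1L, 1L, 1L, 1L, NA, 1L, 2L, 2L, NA, 1L, 1L),
    first_hf_index = c(1L, 1L, NA, 3L, NA, NA, 4L, NA, 1L, NA, 2L, NA),
    stringsAsFactors = FALSE)
  list(histories = histories, expected = expected)
}
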