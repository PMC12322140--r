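# Shared fixtures, built in code and memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function(n, seed, ...) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixtureCache[[key]])) {
    .fixtureCache[[key]] <- generateCohort(simConfig(nPatients = n,
                                                     seed = seed, ...))
  }
  .fixtureCache[[key]]
}

# binary label matrix (NA = excluded) for the GA penalty
labelMatrix <- function(cohort) {
  tob <- function(s) ifelse(s == "excluded", NA, as.numeric(s == "positive"))
  L <- cbind(recurrence = tob(labelStatus(buildRecurrenceLabels(cohort))),
             survival = tob(labelStatus(buildSurvivalLabels(cohort))))
  rownames(L) <- patientIds(cohort)
  L
}

# a minimal valid hand-written record with overrides
makeRecord <- function(id = "001", ...) {
  rec <- list(
    patient_id = id, sex = "male", age_at_diagnosis = 60L,
    smoking_status = "former", primary_site = "larynx", grading = "G2",
    pt_stage = "pT2", pn_stage = "pN0",
    lymphatic_invasion = FALSE, vascular_invasion = FALSE,
    perineural_invasion = FALSE, carcinoma_in_situ = FALSE,
    hpv_positive = FALSE, resection_margin_positive = FALSE,
    blood = list(hemoglobin = list(value = 14.1, unit = "g/dL",
                                   group = "hematology")),
    icd_codes = c("C32.0"),
    tma_density = list(CD3_tumor_center = 500, CD3_invasion_front = 300,
                       CD8_tumor_center = 200, CD8_invasion_front = 100),
    followup_days = 2000L
  )
  over <- list(...)
  for (nm in names(over)) rec[nm] <- over[nm]
  rec
}

# indices of the planted informative instances of a synthetic bag
informativeIdx <- function(bag, frac = 0.1) {
  idx <- integer(0)
  off <- 0L
  for (s in unique(bag@sourceTags)) {
    n <- sum(bag@sourceTags == s)
    idx <- c(idx, off + seq_len(max(1L, round(frac * n))))
    off <- off + n
  }
  idx
}
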