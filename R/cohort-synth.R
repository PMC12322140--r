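# Seeded synthetic-cohort generator.
#
# Emulates the statistical structure the downstream analyses assume:
# marginal demographics of a head-and-neck cancer cohort (~80% male,
# median age ~61 years, ~72% ever-smokers), site-dependent feature
# shifts (confounding), ICD-10 codes drawn from per-site vocabularies,
# blood panel values driven by a latent anomaly score, tissue-microarray
# CD3/CD8 densities driven by a latent immune score, and binary outcomes
# (recurrence, tumor-specific death) from a logistic model whose signal
# is deliberately DISTRIBUTED across modalities, so that early fusion
# beats any single modality by construction. Event days follow a
# discrete-time geometric hazard. Everything is reproducible from one
# seed via documented sub-streams.

.SITE_PROBS_DEFAULT <- c(oral_cavity = 0.30, oropharynx = 0.25,
                         hypopharynx = 0.12, larynx = 0.25, cup = 0.08)

# Site-level shifts (in latent SD units), scaled by siteConfounding:
# stage severity, blood anomaly, immune infiltration, and a direct
# outcome log-odds offset. Oropharyngeal disease (largely HPV-driven) is
# immunologically "hot" with better prognosis; hypopharyngeal disease is
# the opposite.
.SITE_SHIFTS <- list(
  stage   = c(oral_cavity = 0.0, oropharynx = -0.4, hypopharynx = 0.8,
              larynx = 0.1, cup = 0.5),
  blood   = c(oral_cavity = 0.0, oropharynx = -0.3, hypopharynx = 0.6,
              larynx = 0.1, cup = 0.4),
  immune  = c(oral_cavity = 0.0, oropharynx = 0.8, hypopharynx = -0.5,
              larynx = -0.2, cup = 0.0),
  outcome = c(oral_cavity = 0.2, oropharynx = -0.8, hypopharynx = 0.9,
              larynx = 0.0, cup = 0.5)
)

# Per-site primary-diagnosis ICD-10 codes plus shared comorbidity codes.
# Each site also owns one deliberately rare code so that the bag-of-words
# minimum-support filter has codes to drop at realistic cohort sizes.
.ICD_VOCAB_DEFAULT <- list(
  site = list(
    oral_cavity = c("C02.1", "C03.9", "C04.0"),
    oropharynx  = c("C10.8", "C09.9", "C01"),
    hypopharynx = c("C13.9", "C12"),
    larynx      = c("C32.0", "C32.1", "C32.8"),
    cup         = c("C80.0")
  ),
  rare = c(oral_cavity = "C06.2", oropharynx = "C10.4", hypopharynx = "C13.1",
           larynx = "C32.3", cup = "C80.9"),
  comorbidity = c("I10.0", "E11.9", "J44.9", "F10.2", "K70.3",
                  "I25.1", "E78.0", "N18.3")
)

#' Simulation configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: 80% male
#' patients, median age 61 years, 72% ever-smokers, a five-site mix, and
#' outcome effect sizes (per-SD log-odds) split evenly across the four
#' modalities so that fused patient vectors out-predict any single
#' modality by construction.
#'
#' @param nPatients Number of patients (>= 1).
#' @param maleFraction Probability of male sex (default 0.80).
#' @param medianAge Median age at diagnosis in years (default 61).
#' @param smokerFraction Probability of being a former or current smoker
#'   (default 0.72; split 60/40 former/current).
#' @param siteProbs Named probability vector over primary sites (sums to 1).
#' @param outcomeModel Named list of log-odds contributions:
#'   `stage`, `blood`, `immune`, `icd` (per latent SD / per extra
#'   comorbidity code), base rates `recurrenceBase` and `deathBase` on
#'   the logit scale, and `frailty` (log-odds variance of the unmodelled
#'   heterogeneity that replaces the planted signal as a patient's
#'   measured panel becomes anomalous; the immune effect is additionally
#'   modulated by HPV status and site). Setting all effect sizes to 0
#'   reduces outcomes to the base prevalences.
#' @param siteConfounding Strength of the site-feature and site-outcome
#'   association in latent SD units (0 = sites differ only by their ICD
#'   codes; default 1).
#' @param atypicalFraction Fraction of patients belonging to one of
#'   three rare coherent atypical phenotype profiles (default 0.07).
#'   Together with the smooth panel-anomaly signal attenuation (see
#'   `outcomeModel$frailty`), these rare deranged-panel patients are what
#'   makes distributionally extreme held-out sets genuinely harder to
#'   predict.
#' @param missingRates Named per-field missingness probabilities applied
#'   by [injectMissingness()] at generation time. Recognized names:
#'   `flags`, `blood`, `tma_density`, `grading`.
#' @param icdVocab Per-site ICD vocabulary (see package default).
#' @param followupMaxDays Administrative end of follow-up (default 5110
#'   days, i.e. 14 years).
#' @param seed Master seed; all sub-streams derive from it.
#' @return A validated config list of class `SimConfig`.
#' @export
simConfig <- function(nPatients = 200,
                      maleFraction = 0.80,
                      medianAge = 61,
                      smokerFraction = 0.72,
                      siteProbs = .SITE_PROBS_DEFAULT,
                      outcomeModel = list(stage = 1.2, blood = 1.0,
                                          immune = -1.2, icd = 0.9,
                                          frailty = 1.2,
                                          anomalyRisk = 1.0,
                                          recurrenceBase = -1.2,
                                          deathBase = -1.0),
                      siteConfounding = 1,
                      atypicalFraction = 0.07,
                      missingRates = c(flags = 0.03, blood = 0.05,
                                       tma_density = 0.05, grading = 0),
                      icdVocab = .ICD_VOCAB_DEFAULT,
                      followupMaxDays = 5110L,
                      seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), maleFraction = maleFraction,
              medianAge = medianAge, smokerFraction = smokerFraction,
              siteProbs = siteProbs, outcomeModel = outcomeModel,
              siteConfounding = siteConfounding,
              atypicalFraction = atypicalFraction,
              missingRates = missingRates,
              icdVocab = icdVocab, followupMaxDays = as.integer(followupMaxDays),
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  .validateSimConfig(cfg)
  cfg
}

.validateSimConfig <- function(cfg) {
  if (cfg$nPatients < 1L) stop("config error: nPatients must be >= 1")
  pr <- c(cfg$maleFraction, cfg$smokerFraction, cfg$missingRates,
          cfg$atypicalFraction)
  if (any(pr < 0 | pr > 1)) stop("config error: probabilities must lie in [0, 1]")
  if (!setequal(names(cfg$siteProbs), .SITE_LEVELS)) {
    stop("config error: siteProbs must be named by the five primary sites")
  }
  if (abs(sum(cfg$siteProbs) - 1) > 1e-8) {
    stop("config error: siteProbs must sum to 1")
  }
  need <- c("stage", "blood", "immune", "icd", "recurrenceBase", "deathBase")
  if (!all(need %in% names(cfg$outcomeModel))) {
    stop("config error: outcomeModel needs ", paste(need, collapse = ", "))
  }
  invisible(TRUE)
}

#' Generate a synthetic multimodal cohort
#'
#' Draws a fully validated [Cohort] under the configured study
#' conditions. The planted outcome signal is distributed across the four
#' modalities (stage/pathology, blood, TMA immune densities, ICD
#' comorbidity burden); event days are consistent with event status and
#' the follow-up window. Fully reproducible under `config$seed`.
#'
#' @param config A [simConfig()] object.
#' @return A [Cohort] of `config$nPatients` records.
#' @examples
#' cohort <- generateCohort(simConfig(nPatients = 20, seed = 7))
#' length(cohort)
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SimConfig")) config <- do.call(simConfig, config)
  .validateSimConfig(config)
  n <- config$nPatients
  conf <- config$siteConfounding
  om <- config$outcomeModel

  set.seed(.subSeed(config$seed, "demographics"))
  sex <- ifelse(runif(n) < config$maleFraction, "male", "female")
  age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, config$medianAge, 11)))))
  everSmoker <- runif(n) < config$smokerFraction
  smoking <- ifelse(everSmoker,
                    ifelse(runif(n) < 0.6, "former", "current"), "never")
  site <- sample(names(config$siteProbs), n, replace = TRUE,
                 prob = config$siteProbs)

  set.seed(.subSeed(config$seed, "latents"))
  zStage  <- rnorm(n, conf * .SITE_SHIFTS$stage[site], 1)
  zBlood  <- rnorm(n, conf * .SITE_SHIFTS$blood[site], 1)
  zImmune <- rnorm(n, conf * .SITE_SHIFTS$immune[site], 1)
  zCom <- rnorm(n)

  # rare atypical phenotype profiles: a small fraction of patients carry
  # grossly abnormal laboratory/immune panels following one of three
  # coherent clinical patterns (applied to the measured values below),
  # emulating the heavy-tailed rare subgroups real cohorts contain
  set.seed(.subSeed(config$seed, "atypical"))
  pAtyp <- config$atypicalFraction
  profile <- sample(0:3, n, replace = TRUE,
                    prob = c(1 - pAtyp, rep(pAtyp / 3, 3)))

  set.seed(.subSeed(config$seed, "pathology"))
  hpv <- runif(n) < ifelse(site == "oropharynx", 0.55, 0.08)
  zImmune <- zImmune + 0.6 * hpv
  grading <- ifelse(hpv, NA_character_,
                    sample(.GRADING_LEVELS, n, replace = TRUE,
                           prob = c(0.2, 0.5, 0.3)))
  # ordinal stages from the severity latent: monotone binning
  ptLevels <- c("pTis", "pT1", "pT2", "pT3", "pT4", "pT4a", "pT4b")
  ptIdx <- findInterval(zStage + rnorm(n, 0, 0.5),
                        c(-2.2, -1.0, 0.0, 0.9, 1.6, 2.3)) + 1L
  pt <- ptLevels[ptIdx]
  pnIdx <- findInterval(zStage + rnorm(n, 0, 0.7), c(-0.3, 0.8, 1.8)) + 1L
  pn <- c("pN0", "pN1", "pN2", "pN3")[pnIdx]
  flagProb <- plogis(-1.2 + 0.8 * zStage)
  lymphInv <- runif(n) < flagProb
  vascInv <- runif(n) < plogis(-1.8 + 0.7 * zStage)
  periInv <- runif(n) < plogis(-1.5 + 0.7 * zStage)
  cis <- runif(n) < 0.07
  margin <- runif(n) < plogis(-2.0 + 0.6 * zStage)

  set.seed(.subSeed(config$seed, "blood"))
  female <- sex == "female"
  hb  <- rnorm(n, 14.6 - 0.9 * zBlood - 1.1 * female, 1.1)
  ery <- rnorm(n, 4.9 - 0.25 * zBlood - 0.4 * female, 0.4)
  hct <- rnorm(n, 0.43 - 0.02 * zBlood - 0.03 * female, 0.03)
  wbc <- exp(rnorm(n, log(7.2) + 0.18 * zBlood, 0.22))
  plt <- rnorm(n, 265 + 18 * zBlood, 55)
  mcv <- rnorm(n, 90 + 1.5 * zBlood, 4.5)
  mch <- rnorm(n, 30 + 0.5 * zBlood, 1.6)
  mchc <- rnorm(n, 33.5, 1.0)
  crp <- exp(rnorm(n, log(3.0) + 0.55 * zBlood, 0.7))
  sodium <- rnorm(n, 140, 2.5)
  potassium <- rnorm(n, 4.2, 0.35)
  creatinine <- exp(rnorm(n, log(0.95), 0.18))

  set.seed(.subSeed(config$seed, "tma"))
  cd3c <- exp(rnorm(n, log(320) + 0.55 * zImmune, 0.45))
  cd3f <- exp(rnorm(n, log(260) + 0.55 * zImmune, 0.45))
  cd8c <- exp(rnorm(n, log(150) + 0.55 * zImmune, 0.50))
  cd8f <- exp(rnorm(n, log(120) + 0.55 * zImmune, 0.50))

  # apply the atypical panel distortions: per profile a fixed sign
  # pattern over the blood and (log) immune-density panel, shifted by a
  # heavy-tailed multiple of each value's cohort spread
  set.seed(.subSeed(config$seed, "atypical_distortion"))
  if (any(profile > 0L)) {
    panel <- list(hb = hb, ery = ery, hct = hct, wbc = wbc, plt = plt,
                  mcv = mcv, mch = mch, mchc = mchc, crp = crp,
                  sodium = sodium, potassium = potassium,
                  creatinine = creatinine)
    # three syndromes with mutually opposing panel signatures (pairwise
    # anti-correlated patterns), so the rare deranged patients are far
    # from the bulk AND from each other's groups
    signs <- rbind(
      # reactive hyperproliferation: erythro-, leuko- and thrombocytosis
      # with strong immune infiltration
      c(hb = 1, ery = 1, hct = 1, wbc = 1, plt = 1, mcv = 1, mch = 1,
        mchc = 1, crp = 1, sodium = -1, potassium = 1, creatinine = 1,
        tma = 1),
      # macrocytic anemia with reactive thrombocytosis, immune-cold
      c(hb = -1, ery = -1, hct = -1, wbc = -1, plt = 1, mcv = 1, mch = 1,
        mchc = 1, crp = 1, sodium = -1, potassium = -1, creatinine = -1,
        tma = -1),
      # pancytopenic marrow suppression with immune infiltration
      c(hb = -1, ery = -1, hct = -1, wbc = -1, plt = -1, mcv = -1,
        mch = -1, mchc = -1, crp = -1, sodium = 1, potassium = 1,
        creatinine = 1, tma = 1)
    )
    spreads <- vapply(panel, sd, numeric(1))
    for (i in which(profile > 0L)) {
      k <- profile[i]
      gamma <- 4 + abs(rnorm(1, 0, 0.7))
      for (pname in names(panel)) {
        sgn <- signs[k, pname]
        if (sgn != 0) {
          panel[[pname]][i] <- panel[[pname]][i] + sgn * gamma * spreads[[pname]]
        }
      }
      tmaFactor <- exp(signs[k, "tma"] * gamma * 0.5)
      cd3c[i] <- cd3c[i] * tmaFactor
      cd3f[i] <- cd3f[i] * tmaFactor
      cd8c[i] <- cd8c[i] * tmaFactor
      cd8f[i] <- cd8f[i] * tmaFactor
    }
    panel <- lapply(panel, function(v) pmax(v, 0.01))
    hb <- panel$hb; ery <- panel$ery; hct <- panel$hct; wbc <- panel$wbc
    plt <- panel$plt; mcv <- panel$mcv; mch <- panel$mch; mchc <- panel$mchc
    crp <- panel$crp; sodium <- panel$sodium; potassium <- panel$potassium
    creatinine <- panel$creatinine
  }

  set.seed(.subSeed(config$seed, "icd"))
  nCom <- rpois(n, lambda = pmax(0.2, 1 + 0.6 * zCom))
  icdCodes <- vector("list", n)
  for (i in seq_len(n)) {
    siteCodes <- config$icdVocab$site[[site[i]]]
    k <- min(length(siteCodes), 1L + (runif(1) < 0.35))
    codes <- sample(siteCodes, k)
    com <- config$icdVocab$comorbidity
    codes <- c(codes, sample(com, min(nCom[i], length(com))))
    if (runif(1) < 0.008) codes <- c(codes, config$icdVocab$rare[[site[i]]])
    icdCodes[[i]] <- sort(unique(codes))
  }

  set.seed(.subSeed(config$seed, "outcomes"))
  # effect modification: immune infiltration is strongly protective in
  # HPV-driven disease and weakly protective otherwise; in the largely
  # HPV-driven oropharynx, anatomical stage and systemic blood anomalies
  # carry much less prognostic weight than elsewhere. Outcomes of
  # atypical-profile patients are only weakly coupled to the measured
  # features (their drivers are unmeasured) and carry extra
  # heterogeneity.
  bImm <- ifelse(hpv, om$immune * 1.6, om$immune * 0.45)
  oroph <- site == "oropharynx"
  bStage <- om$stage * ifelse(oroph, 0.12, 1)
  bBlood <- om$blood * ifelse(oroph, 0.2, 1)
  bIcd <- om$icd * ifelse(oroph, 0.3, 1)
  lin <- bStage * zStage + bBlood * zBlood + bImm * zImmune +
    bIcd * (nCom - 1) / 1.2 + conf * .SITE_SHIFTS$outcome[site]
  # panel anomaly: root-mean-square cohort z-score over the measured
  # hematology, immune-density and age values. The further a patient's
  # measured panel lies from the cohort bulk, the more the outcome is
  # dominated by unmodelled acute illness instead of tumor biology:
  # the planted signal attenuates smoothly and heterogeneity grows.
  panelZ <- cbind(age, hb, ery, hct, wbc, plt, mcv, mch, mchc,
                  log(cd3c), log(cd3f), log(cd8c), log(cd8f))
  panelZ <- sweep(sweep(panelZ, 2, colMeans(panelZ)), 2,
                  apply(panelZ, 2, sd), "/")
  anomaly <- sqrt(rowMeans(panelZ^2))
  retain <- plogis(4 * (1.1 - anomaly))
  frailtyVar <- if (is.null(om$frailty)) 0 else max(0, om$frailty)
  # deranged patients are acutely sicker (risk rises toward 50/50 events)
  # while their individual outcomes decouple from the tumor features
  anomalyRisk <- if (is.null(om$anomalyRisk)) 1.0 else om$anomalyRisk
  lin <- retain * lin + (1 - retain) * anomalyRisk +
    rnorm(n, 0, sqrt(frailtyVar) * (1 - retain))
  pRec <- plogis(om$recurrenceBase + lin)
  recurs <- runif(n) < pRec
  recurrenceDays <- ifelse(recurs, 30L + rgeom(n, 1 / 420), NA_integer_)

  pDeath <- plogis(om$deathBase + lin + 0.8 * recurs)
  tumorDeath <- runif(n) < pDeath
  otherDeath <- runif(n) < 0.06
  deathDays <- rep(NA_integer_, n)
  dts <- rep(NA, n)
  tumorDeathDay <- pmin(config$followupMaxDays,
                        60L + rgeom(n, 1 / 650) +
                          ifelse(recurs, pmax(0L, recurrenceDays - 30L), 0L))
  otherDeathDay <- as.integer(round(runif(n, 100, config$followupMaxDays)))
  for (i in seq_len(n)) {
    if (tumorDeath[i] && (!otherDeath[i] || tumorDeathDay[i] <= otherDeathDay[i])) {
      deathDays[i] <- tumorDeathDay[i]
      dts[i] <- if (runif(1) < 0.85) TRUE else NA  # some unknown causes
    } else if (otherDeath[i]) {
      deathDays[i] <- otherDeathDay[i]
      dts[i] <- FALSE
    }
  }
  followup <- ifelse(!is.na(deathDays), deathDays,
                     ifelse(runif(n) < 0.85,
                            as.integer(round(runif(n, 1200, config$followupMaxDays))),
                            as.integer(round(runif(n, 200, 1094)))))
  # recurrences reported only if observed within follow-up
  recurrenceDays[!is.na(recurrenceDays) & recurrenceDays > followup] <- NA_integer_

  pad <- max(3L, nchar(as.character(n)))
  ids <- formatC(seq_len(n), width = pad, flag = "0")
  bloodEntry <- function(v, unit, group) list(value = v, unit = unit, group = group)
  recordsList <- vector("list", n)
  for (i in seq_len(n)) {
    recordsList[[i]] <- list(
      patient_id = ids[i],
      sex = sex[i],
      age_at_diagnosis = age[i],
      smoking_status = smoking[i],
      primary_site = site[i],
      grading = if (is.na(grading[i])) NULL else grading[i],
      pt_stage = pt[i],
      pn_stage = pn[i],
      lymphatic_invasion = lymphInv[i],
      vascular_invasion = vascInv[i],
      perineural_invasion = periInv[i],
      carcinoma_in_situ = cis[i],
      hpv_positive = hpv[i],
      resection_margin_positive = margin[i],
      blood = list(
        hemoglobin = bloodEntry(round(hb[i], 2), "g/dL", "hematology"),
        erythrocytes = bloodEntry(round(ery[i], 2), "10^6/uL", "hematology"),
        leukocytes = bloodEntry(round(wbc[i], 2), "10^3/uL", "hematology"),
        platelets = bloodEntry(round(plt[i], 1), "10^3/uL", "hematology"),
        hematocrit = bloodEntry(round(hct[i], 3), "L/L", "hematology"),
        mcv = bloodEntry(round(mcv[i], 1), "fL", "hematology"),
        mch = bloodEntry(round(mch[i], 1), "pg", "hematology"),
        mchc = bloodEntry(round(mchc[i], 1), "g/dL", "hematology"),
        crp = bloodEntry(round(crp[i], 2), "mg/L", "inflammation"),
        sodium = bloodEntry(round(sodium[i], 1), "mmol/L", "electrolytes"),
        potassium = bloodEntry(round(potassium[i], 2), "mmol/L", "electrolytes"),
        creatinine = bloodEntry(round(creatinine[i], 2), "mg/dL", "renal")
      ),
      icd_codes = icdCodes[[i]],
      tma_density = list(
        CD3_tumor_center = round(cd3c[i], 1),
        CD3_invasion_front = round(cd3f[i], 1),
        CD8_tumor_center = round(cd8c[i], 1),
        CD8_invasion_front = round(cd8f[i], 1)
      ),
      recurrence_days = if (is.na(recurrenceDays[i])) NULL else as.integer(recurrenceDays[i]),
      death_days = if (is.na(deathDays[i])) NULL else as.integer(deathDays[i]),
      death_tumor_specific = if (is.na(dts[i])) NULL else dts[i],
      followup_days = as.integer(followup[i])
    )
  }
  cohort <- newCohort(recordsList)
  if (any(config$missingRates > 0)) {
    cohort <- injectMissingness(cohort, config$missingRates,
                                seed = .subSeed(config$seed, "missingness"))
  }
  cohort
}

#' Blank eligible fields at configured rates
#'
#' Each eligible field is independently set missing with its rate.
#' `patient_id` and the outcome/event fields are never blanked.
#' Recognized rate names: `flags` (the six tri-state pathology flags),
#' `blood` (per blood parameter), `tma_density` (per density entry) and
#' `grading`.
#'
#' @param cohort A [Cohort].
#' @param rates Named numeric vector of probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return A new [Cohort] with injected missingness.
#' @export
injectMissingness <- function(cohort, rates, seed = 1L) {
  stopifnot(is(cohort, "Cohort"))
  rates <- unlist(rates)
  if (any(rates < 0 | rates > 1)) stop("config error: rates must lie in [0, 1]")
  known <- c("flags", "blood", "tma_density", "grading")
  if (!all(names(rates) %in% known)) {
    stop("config error: unknown rate name(s): ",
         paste(setdiff(names(rates), known), collapse = ", "))
  }
  r <- function(nm) if (nm %in% names(rates)) rates[[nm]] else 0
  set.seed(seed)
  recs <- lapply(cohort@records, function(rec) {
    for (f in .FLAG_FIELDS) {
      if (runif(1) < r("flags")) rec[f] <- list(NULL)
    }
    if (!is.null(rec$blood) && length(rec$blood)) {
      keep <- runif(length(rec$blood)) >= r("blood")
      rec$blood <- rec$blood[keep]
    }
    if (!is.null(rec$tma_density) && length(rec$tma_density)) {
      for (k in names(rec$tma_density)) {
        if (runif(1) < r("tma_density")) rec$tma_density[k] <- list(NULL)
      }
    }
    if (!is.null(rec$grading) && runif(1) < r("grading")) {
      rec["grading"] <- list(NULL)
    }
    rec
  })
  newCohort(recs, cohort@schemaVersion)
}

#' Plant feature-space outliers
#'
#' Shifts every numeric feature (age, blood values, TMA densities) of `k`
#' randomly chosen patients by `scale` times that feature's cohort
#' standard deviation, with an independent random sign per patient and
#' feature. Densities are clamped at zero. Returns the planted IDs for
#' ground-truth checks of out-of-distribution split behaviour.
#'
#' @param cohort A [Cohort].
#' @param k Number of outliers (0 <= k <= n).
#' @param scale Shift magnitude in per-feature SD units.
#' @param seed Integer seed.
#' @return `list(cohort = <Cohort>, outlierIds = <character>)`.
#' @export
plantOutliers <- function(cohort, k, scale = 5, seed = 1L) {
  stopifnot(is(cohort, "Cohort"))
  n <- length(cohort)
  if (k > n) stop("argument error: k exceeds the cohort size")
  if (k == 0L) return(list(cohort = cohort, outlierIds = character(0)))
  set.seed(seed)
  ids <- patientIds(cohort)
  chosen <- sort(sample(ids, k))

  num <- function(get) vapply(cohort@records, function(r) {
    v <- get(r); if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  spreads <- list(
    age = sd(num(function(r) r$age_at_diagnosis), na.rm = TRUE)
  )
  bloodParams <- unique(unlist(lapply(cohort@records, function(r) names(r$blood))))
  for (p in bloodParams) {
    spreads[[paste0("blood.", p)]] <-
      sd(num(function(r) r$blood[[p]]$value), na.rm = TRUE)
  }
  for (kk in .TMA_KEYS) {
    spreads[[paste0("tma.", kk)]] <-
      sd(num(function(r) r$tma_density[[kk]]), na.rm = TRUE)
  }
  shift <- function(v, spread) {
    if (is.null(v) || is.na(spread) || spread == 0) return(v)
    v + sample(c(-1, 1), 1) * scale * spread
  }
  recs <- lapply(cohort@records, function(rec) {
    if (!(rec$patient_id %in% chosen)) return(rec)
    rec$age_at_diagnosis <- as.integer(max(0, round(
      shift(rec$age_at_diagnosis, spreads$age))))
    for (p in names(rec$blood)) {
      rec$blood[[p]]$value <- shift(rec$blood[[p]]$value,
                                    spreads[[paste0("blood.", p)]])
    }
    for (kk in names(rec$tma_density)) {
      v <- shift(rec$tma_density[[kk]], spreads[[paste0("tma.", kk)]])
      if (!is.null(v)) rec$tma_density[[kk]] <- max(0, v)
    }
    rec
  })
  list(cohort = newCohort(recs, cohort@schemaVersion), outlierIds = chosen)
}
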