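#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData assay
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm runif rbinom rgeom rpois quantile sd var median
#'   plogis setNames approx pnorm dist predict
#' @importFrom utils combn head
NULL

# ---- Controlled vocabularies of the record schema ----------------------

.SEX_LEVELS <- c("male", "female")
.SMOKING_LEVELS <- c("never", "former", "current", "unknown")
.SITE_LEVELS <- c("oral_cavity", "oropharynx", "hypopharynx", "larynx", "cup")
.GRADING_LEVELS <- c("G1", "G2", "G3")

# Ordinal decision tables: consecutive severity labels for pathological
# T and N stage. pN2 sub-stages collapse to one level by default.
.PT_TABLE <- c(pTis = 0, pT1 = 1, pT2 = 2, pT3 = 3, pT4 = 4, pT4a = 5, pT4b = 6)
.PN_TABLE <- c(pN0 = 0, pN1 = 1, pN2 = 2, pN2a = 2, pN2b = 2, pN2c = 2, pN3 = 3)

.FLAG_FIELDS <- c("lymphatic_invasion", "vascular_invasion",
                  "perineural_invasion", "carcinoma_in_situ",
                  "hpv_positive", "resection_margin_positive")

.TMA_KEYS <- c("CD3_tumor_center", "CD3_invasion_front",
               "CD8_tumor_center", "CD8_invasion_front")

# Fixed serialization order of record fields.
.RECORD_FIELDS <- c("patient_id", "sex", "age_at_diagnosis", "smoking_status",
                    "primary_site", "grading", "pt_stage", "pn_stage",
                    .FLAG_FIELDS, "blood", "icd_codes", "tma_density",
                    "recurrence_days", "death_days", "death_tumor_specific",
                    "followup_days")

.SCHEMA_VERSION <- "1.0"

# ---- Core S4 classes ---------------------------------------------------

#' Cohort of patient-centered multimodal records
#'
#' An ordered collection of validated patient records. Records are plain
#' named lists (one per patient) holding demographics, pathological
#' features, blood panel values, ICD-10 codes, tissue-microarray immune
#' cell densities and the event timeline in days since initial diagnosis.
#' Records are kept sorted by `patient_id` and IDs are unique.
#'
#' @slot records A list of patient records (named lists).
#' @slot schemaVersion Character scalar, schema version of the records.
#' @seealso [readCohort()], [writeCohort()], [generateCohort()]
#' @export
setClass("Cohort",
  representation(records = "list", schemaVersion = "character"),
  prototype(records = list(), schemaVersion = .SCHEMA_VERSION)
)

setValidity("Cohort", function(object) {
  probs <- character(0)
  ids <- vapply(object@records, function(r) {
    id <- r[["patient_id"]]
    if (is.null(id)) NA_character_ else as.character(id)
  }, character(1))
  if (anyNA(ids)) probs <- c(probs, "record(s) without patient_id")
  if (anyDuplicated(ids)) {
    probs <- c(probs, sprintf("duplicate patient_id: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (is.unsorted(ids, strictly = FALSE)) {
    probs <- c(probs, "records must be sorted by patient_id")
  }
  for (r in object@records) {
    rp <- .validateRecord(r)
    if (length(rp)) {
      probs <- c(probs, sprintf("patient %s: %s",
                                as.character(r[["patient_id"]]),
                                paste(rp, collapse = "; ")))
    }
    if (length(probs) > 10L) break
  }
  if (length(probs)) paste(probs, collapse = "\n") else TRUE
})

#' Multimodal patient vectors
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one column per
#' patient and one row per (post one-hot expansion) feature. `rowData`
#' carries each feature's name, modality
#' (`clinical_pathological`, `blood`, `icd`, `tma`) and kind (`binary`,
#' `ordinal`, `categorical_label`, `numeric`, `bow`). `colData` records
#' the pre-imputation completeness flag. `metadata()$preExpansionDim`
#' reports the feature count before one-hot expansion.
#'
#' @seealso [assembleVectors()], [featureModality()], [isComplete()]
#' @export
setClass("PatientVectors", contains = "SummarizedExperiment")

#' Fitted per-cohort encoding state
#'
#' Holds everything data-dependent about the patient-vector encoding:
#' ICD vocabulary, observed categorical levels, per-feature imputation
#' values and z-score centering/scaling. Fit on a training subset, it can
#' be applied to held-out patients without information leakage.
#'
#' @slot schema Encoding schema (see [defaultSchema()]).
#' @slot vocabulary Character vector of retained 4-character ICD prefixes.
#' @slot levels Named list of observed levels per categorical feature.
#' @slot imputeValues Named list of per-feature imputation values.
#' @slot center,scale Named numeric vectors of z-score statistics for the
#'   scaled (ordinal and numeric) columns.
#' @export
setClass("Vectorizer",
  representation(schema = "list", vocabulary = "character", levels = "list",
                 imputeValues = "list", center = "numeric", scale = "numeric")
)

#' One modality's features for a single patient
#'
#' @slot modality One of `clinical_pathological`, `blood`, `icd`, `tma`.
#' @slot names Feature names (unique within the block).
#' @slot values Numeric values aligned to `names`; `NA` marks missing.
#' @slot kind Per-feature kind: `binary`, `ordinal`, `categorical_label`,
#'   `numeric` or `bow`.
#' @export
setClass("FeatureBlock",
  representation(modality = "character", names = "character",
                 values = "numeric", kind = "character")
)

setValidity("FeatureBlock", function(object) {
  if (length(object@names) != length(object@values) ||
      length(object@names) != length(object@kind)) {
    return("names, values and kind must have equal length")
  }
  if (anyDuplicated(object@names)) return("feature names must be unique")
  TRUE
})

#' Genetic-algorithm split problem
#'
#' Precomputed state for the evolutionary train/test split: the imputed,
#' encoded patient-vector matrix restricted to eligible (complete-vector)
#' patients, its cosine-similarity matrix, binary outcome labels used by
#' the class-balance penalty, the test-set cardinality N and the penalty
#' weight alpha.
#'
#' @slot X Numeric matrix, eligible patients x features.
#' @slot S Cosine similarity matrix over eligible patients.
#' @slot labels Numeric matrix (eligible patients x C) of binary targets;
#'   `NA` excludes a patient from the penalty for that class.
#' @slot dAll Overall positive fraction per class.
#' @slot N Test-set size.
#' @slot alpha Penalty weight.
#' @slot mode `"in_distribution"` or `"out_of_distribution"`.
#' @slot eligibleIds,ineligibleIds Patient IDs inside/outside the GA.
#' @export
setClass("SplitProblem",
  representation(X = "matrix", S = "matrix", labels = "matrix",
                 dAll = "numeric", N = "integer", alpha = "numeric",
                 mode = "character", eligibleIds = "character",
                 ineligibleIds = "character")
)

#' Result of a train/test split
#'
#' @slot trainIds,testIds Patient IDs; a partition of the cohort.
#' @slot bestFitness Fitness of the returned split (`NA` for
#'   deterministic splits such as the site holdout).
#' @slot trace Best-so-far fitness per generation (non-decreasing).
#' @slot mode Split regime label.
#' @export
setClass("SplitResult",
  representation(trainIds = "character", testIds = "character",
                 bestFitness = "numeric", trace = "numeric", mode = "character")
)

setValidity("SplitResult", function(object) {
  if (length(intersect(object@trainIds, object@testIds)) > 0L) {
    return("train and test IDs overlap")
  }
  TRUE
})

#' Outcome label assignment
#'
#' Every patient of the cohort is assigned exactly one state:
#' `positive`, `negative` or `excluded` (with a reason).
#'
#' @slot task Label-construction task identifier.
#' @slot patientIds Cohort patient IDs.
#' @slot status Factor with levels positive/negative/excluded.
#' @slot reason Exclusion reason (`""` for included patients).
#' @export
setClass("OutcomeLabels",
  representation(task = "character", patientIds = "character",
                 status = "factor", reason = "character")
)

setValidity("OutcomeLabels", function(object) {
  if (length(object@patientIds) != length(object@status) ||
      length(object@patientIds) != length(object@reason)) {
    return("patientIds, status and reason must align")
  }
  if (!identical(levels(object@status), c("positive", "negative", "excluded"))) {
    return("status levels must be positive/negative/excluded")
  }
  TRUE
})

#' Bag of instance embeddings for multiple instance learning
#'
#' @slot patientId Patient the bag belongs to.
#' @slot instances Numeric matrix, instances x embedding dimension.
#' @slot sourceTags Per-instance source (`WSI` or `TMA:<stain>`).
#' @slot label Bag label (0/1) or `NA` when unknown.
#' @export
setClass("Bag",
  representation(patientId = "character", instances = "matrix",
                 sourceTags = "character", label = "numeric")
)

setValidity("Bag", function(object) {
  if (nrow(object@instances) < 1L) return("a bag needs at least one instance")
  if (length(object@sourceTags) != nrow(object@instances)) {
    return("one source tag per instance required")
  }
  TRUE
})

#' Trained gated-attention MIL model
#'
#' @slot weights Named list of parameter matrices/vectors.
#' @slot params Training parameters (see [milParams()]).
#' @slot lossTrace Data frame of per-epoch bag and instance losses.
#' @export
setClass("MILModel",
  representation(weights = "list", params = "list", lossTrace = "data.frame")
)

#' Attention result for one bag
#'
#' @slot instanceWeights Normalized attention weights (sum to 1).
#' @slot bagScore Positive-class probability of the bag.
#' @slot sourceTags Per-instance source tags.
#' @export
setClass("AttentionResult",
  representation(instanceWeights = "numeric", bagScore = "numeric",
                 sourceTags = "character")
)

#' Kaplan-Meier product-limit curve
#'
#' @slot time Distinct observed times (days).
#' @slot surv Survival probability step function values.
#' @slot nRisk,nEvent,nCensor At-risk / event / censoring counts.
#' @slot lower,upper Pointwise 95% confidence band (Greenwood, log scale).
#' @slot maxTime Largest observed time; lookups beyond it extrapolate.
#' @export
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", nRisk = "numeric",
                 nEvent = "numeric", nCensor = "numeric",
                 lower = "numeric", upper = "numeric", maxTime = "numeric")
)

setValidity("KMCurve", function(object) {
  if (any(diff(object@surv) > 1e-12)) return("survival must be non-increasing")
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12)) {
    return("survival probabilities must lie in [0, 1]")
  }
  TRUE
})

# ---- Generics ----------------------------------------------------------

#' Patient identifiers of an object
#' @param x A Cohort, PatientVectors, OutcomeLabels or SplitResult.
#' @return Character vector of patient IDs.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' Per-feature modality tags of a PatientVectors object
#' @param x A PatientVectors object.
#' @export
setGeneric("featureModality", function(x) standardGeneric("featureModality"))

#' Per-feature kind tags of a PatientVectors object
#' @param x A PatientVectors object.
#' @export
setGeneric("featureKind", function(x) standardGeneric("featureKind"))

#' Pre-imputation completeness flags
#' @param x A PatientVectors object.
#' @return Named logical vector: were all required modalities present
#'   before imputation?
#' @export
setGeneric("isComplete", function(x) standardGeneric("isComplete"))

#' Patients x features matrix of a PatientVectors object
#' @param x A PatientVectors object.
#' @export
setGeneric("vectorMatrix", function(x) standardGeneric("vectorMatrix"))

#' Records of a Cohort
#' @param x A Cohort.
#' @return List of patient records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Train patient IDs of a split
#' @param x A SplitResult.
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' Test patient IDs of a split
#' @param x A SplitResult.
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' Label status vector
#' @param x An OutcomeLabels object.
#' @return Named factor (positive/negative/excluded) indexed by patient ID.
#' @export
setGeneric("labelStatus", function(x) standardGeneric("labelStatus"))

# ---- Methods: Cohort ---------------------------------------------------

#' @describeIn Cohort Number of patients.
#' @param x A Cohort.
#' @export
setMethod("length", "Cohort", function(x) length(x@records))

#' @describeIn Cohort Patient identifiers, in record order.
#' @export
setMethod("patientIds", "Cohort", function(x) {
  vapply(x@records, function(r) as.character(r[["patient_id"]]), character(1))
})

#' @describeIn Cohort Access the record list.
#' @export
setMethod("records", "Cohort", function(x) x@records)

#' @describeIn Cohort Subset by integer index, logical mask or patient ID.
#' @param i Index, logical mask or character vector of patient IDs.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "Cohort", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) {
    idx <- match(i, patientIds(x))
    if (anyNA(idx)) stop("unknown patient ID(s): ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- sort(idx)
  } else if (is.logical(i)) {
    i <- which(i)
  } else {
    i <- sort(i)
  }
  new("Cohort", records = x@records[i], schemaVersion = x@schemaVersion)
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort with %d patient record(s), schema %s\n",
              length(object), object@schemaVersion))
  if (length(object)) {
    ids <- patientIds(object)
    cat(sprintf("  patient IDs: %s%s\n",
                paste(head(ids, 5), collapse = ", "),
                if (length(ids) > 5) ", ..." else ""))
  }
})

# ---- Methods: PatientVectors -------------------------------------------

#' @describeIn PatientVectors Patient IDs (column names).
#' @param x A PatientVectors object.
#' @export
setMethod("patientIds", "PatientVectors", function(x) colnames(x))

#' @describeIn PatientVectors Per-feature modality tags.
#' @export
setMethod("featureModality", "PatientVectors", function(x) {
  as.character(SummarizedExperiment::rowData(x)$modality)
})

#' @describeIn PatientVectors Per-feature kind tags.
#' @export
setMethod("featureKind", "PatientVectors", function(x) {
  as.character(SummarizedExperiment::rowData(x)$kind)
})

#' @describeIn PatientVectors Pre-imputation completeness flags.
#' @export
setMethod("isComplete", "PatientVectors", function(x) {
  setNames(SummarizedExperiment::colData(x)$complete, colnames(x))
})

#' @describeIn PatientVectors Patients x features numeric matrix.
#' @export
setMethod("vectorMatrix", "PatientVectors", function(x) {
  t(SummarizedExperiment::assay(x, "vectors"))
})

# ---- Methods: SplitResult ----------------------------------------------

#' @describeIn SplitResult Training-set patient IDs.
#' @param x A SplitResult.
#' @export
setMethod("trainIds", "SplitResult", function(x) x@trainIds)

#' @describeIn SplitResult Test-set patient IDs.
#' @export
setMethod("testIds", "SplitResult", function(x) x@testIds)

#' @describeIn SplitResult All patient IDs (train, then test).
#' @export
setMethod("patientIds", "SplitResult", function(x) c(x@trainIds, x@testIds))

setMethod("show", "SplitResult", function(object) {
  cat(sprintf("SplitResult (%s): %d train / %d test, fitness %s\n",
              object@mode, length(object@trainIds), length(object@testIds),
              format(object@bestFitness, digits = 6)))
})

# ---- Methods: OutcomeLabels --------------------------------------------

#' @describeIn OutcomeLabels Patient IDs.
#' @param x An OutcomeLabels object.
#' @export
setMethod("patientIds", "OutcomeLabels", function(x) x@patientIds)

#' @describeIn OutcomeLabels Named status factor.
#' @export
setMethod("labelStatus", "OutcomeLabels", function(x) {
  setNames(x@status, x@patientIds)
})

setMethod("show", "OutcomeLabels", function(object) {
  tab <- table(object@status)
  cat(sprintf("OutcomeLabels[%s]: %d positive, %d negative, %d excluded\n",
              object@task, tab[["positive"]], tab[["negative"]],
              tab[["excluded"]]))
})

setMethod("show", "Bag", function(object) {
  cat(sprintf("Bag for patient %s: %d instance(s) x %d dims, label %s\n",
              object@patientId, nrow(object@instances),
              ncol(object@instances), format(object@label)))
  print(table(object@sourceTags))
})

setMethod("show", "MILModel", function(object) {
  n <- nrow(object@lossTrace)
  cat(sprintf("MILModel: gated attention (hidden %d), %d epoch(s), final bag loss %.4f\n",
              object@params$hidden, n,
              if (n) object@lossTrace$bagLoss[n] else NA_real_))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve: %d time point(s), final S(t) = %.3f at t = %g days\n",
              length(object@time),
              if (length(object@surv)) object@surv[length(object@surv)] else 1,
              object@maxTime))
})
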