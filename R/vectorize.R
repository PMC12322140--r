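# Per-modality encoding, imputation, normalization, concatenation into
# multimodal patient vectors, and 2-D projection.
#
# Encoding rules: binary flags -> {0, 1, NA}; pT/pN stage -> consecutive
# ordinal labels via the shipped decision tables; categorical features ->
# integer labels, expanded one-hot (pure indicator, no reference-level
# drop) at assembly; blood -> raw values of the hematology panel (the
# complete blood count); ICD codes -> bag-of-words over 4-character code
# prefixes kept at minimum support; TMA -> the four CD3/CD8 densities.
# Imputation: per-feature mode (binary/categorical) or mean
# (numeric/ordinal). Ordinal + numeric columns are z-scored.

#' Default encoding schema
#'
#' Describes the structured clinical/pathological features (name, kind,
#' levels), the hematology panel used for raw blood values, and the
#' ICD bag-of-words minimum support.
#'
#' @param bloodPanel Hematology parameter names included as raw values.
#' @param minSupport Minimum number of carrying patients for an ICD code
#'   prefix to enter the vocabulary (default 3).
#' @return A schema list.
#' @export
defaultSchema <- function(bloodPanel = c("hemoglobin", "erythrocytes",
                                         "leukocytes", "platelets",
                                         "hematocrit", "mcv", "mch", "mchc"),
                          minSupport = 3L) {
  list(
    structured = list(
      sex = list(kind = "categorical_label", levels = .SEX_LEVELS),
      age_at_diagnosis = list(kind = "numeric"),
      smoking_status = list(kind = "categorical_label", levels = .SMOKING_LEVELS),
      primary_site = list(kind = "categorical_label", levels = .SITE_LEVELS),
      grading = list(kind = "categorical_label", levels = .GRADING_LEVELS),
      pt_stage = list(kind = "ordinal", table = .PT_TABLE),
      pn_stage = list(kind = "ordinal", table = .PN_TABLE),
      lymphatic_invasion = list(kind = "binary"),
      vascular_invasion = list(kind = "binary"),
      perineural_invasion = list(kind = "binary"),
      carcinoma_in_situ = list(kind = "binary"),
      hpv_positive = list(kind = "binary"),
      resection_margin_positive = list(kind = "binary")
    ),
    bloodPanel = bloodPanel,
    minSupport = as.integer(minSupport)
  )
}

#' Encode structured clinical/pathological features of one patient
#'
#' Binary flags become 0/1 (NA when missing); pT/pN stages become
#' consecutive ordinal integers via the schema decision tables;
#' categorical features become integer labels (their one-hot expansion
#' happens at assembly); age stays numeric.
#'
#' @param record A patient record (named list) from a validated [Cohort].
#' @param schema Encoding schema, see [defaultSchema()].
#' @return A [FeatureBlock] with modality `clinical_pathological`.
#' @export
encodeStructured <- function(record, schema = defaultSchema()) {
  feats <- schema$structured
  vals <- numeric(length(feats))
  kinds <- character(length(feats))
  nms <- names(feats)
  for (i in seq_along(feats)) {
    f <- nms[i]
    sp <- feats[[i]]
    v <- .fieldOrNA(record, f)
    kinds[i] <- sp$kind
    if (length(v) == 1L && is.na(v)) {
      vals[i] <- NA_real_
      next
    }
    vals[i] <- switch(sp$kind,
      binary = as.numeric(as.logical(v)),
      ordinal = {
        if (!v %in% names(sp$table)) {
          stop(sprintf("validation error: %s level %s absent from decision table",
                       f, deparse(v)))
        }
        unname(sp$table[[v]])
      },
      categorical_label = {
        if (!v %in% sp$levels) {
          stop(sprintf("validation error: %s level %s outside declared levels",
                       f, deparse(v)))
        }
        match(v, sp$levels)
      },
      numeric = as.numeric(v),
      stop("unknown feature kind: ", sp$kind)
    )
  }
  new("FeatureBlock", modality = "clinical_pathological", names = nms,
      values = vals, kind = kinds)
}

#' Encode blood panel values of one patient
#'
#' Returns the raw values of the hematology panel (the complete blood
#' count) in panel order. Parameters outside the panel (e.g. CRP,
#' electrolytes) are excluded; absent parameters are missing.
#'
#' @param record A patient record.
#' @param panel Hematology parameter names.
#' @return A [FeatureBlock] with modality `blood`.
#' @export
encodeBlood <- function(record, panel = defaultSchema()$bloodPanel) {
  vals <- vapply(panel, function(p) {
    e <- record$blood[[p]]
    if (is.null(e)) NA_real_ else as.numeric(e$value)
  }, numeric(1))
  new("FeatureBlock", modality = "blood", names = paste0("blood.", panel),
      values = unname(vals), kind = rep("numeric", length(panel)))
}

# Truncate an ICD code to its category level: the literal first four
# characters of the string, dot included ("C32.0" -> "C32.").
.icdPrefix <- function(codes) substr(codes, 1L, 4L)

#' Fit the ICD bag-of-words vocabulary and per-patient count vectors
#'
#' Each code is truncated to its first four characters; truncated codes
#' carried by at least `minSupport` patients form the vocabulary (sorted
#' lexicographically). Per patient, the block holds occurrence counts
#' over the vocabulary.
#'
#' @param cohort A [Cohort] (non-empty).
#' @param minSupport Minimum number of carrying patients (default 3).
#' @return `list(vocabulary = <character>, counts = <matrix>)` with one
#'   count row per patient (rownames = patient IDs).
#' @examples
#' # four patients; C10. is carried by only 2 patients and is dropped
#' @export
encodeICD <- function(cohort, minSupport = 3L) {
  stopifnot(is(cohort, "Cohort"), length(cohort) >= 1L)
  ids <- patientIds(cohort)
  perPatient <- lapply(records(cohort), function(r) {
    codes <- r$icd_codes
    if (is.null(codes) || length(codes) == 0L) character(0)
    else .icdPrefix(as.character(unlist(codes)))
  })
  support <- table(unlist(lapply(perPatient, unique)))
  vocabulary <- sort(names(support)[support >= minSupport])
  counts <- icdCounts(cohort, vocabulary)
  list(vocabulary = vocabulary, counts = counts)
}

#' Count ICD code prefixes against a fixed vocabulary
#'
#' Applies an already-fitted vocabulary (e.g. fitted on training
#' patients only) to any cohort; codes outside the vocabulary are
#' ignored.
#'
#' @param cohort A [Cohort].
#' @param vocabulary Character vector of 4-character code prefixes.
#' @return Integer matrix, patients x vocabulary.
#' @export
icdCounts <- function(cohort, vocabulary) {
  ids <- patientIds(cohort)
  counts <- matrix(0L, nrow = length(ids), ncol = length(vocabulary),
                   dimnames = list(ids, vocabulary))
  for (i in seq_along(ids)) {
    codes <- records(cohort)[[i]]$icd_codes
    if (is.null(codes) || length(codes) == 0L) next
    pref <- .icdPrefix(as.character(unlist(codes)))
    tab <- table(pref[pref %in% vocabulary])
    if (length(tab)) counts[i, names(tab)] <- as.integer(tab)
  }
  counts
}

#' Encode TMA immune-cell densities of one patient
#'
#' Four numeric features: CD3 and CD8 positive-cell densities
#' (cells/mm^2) in the tumor center and at the invasion front.
#'
#' @param record A patient record.
#' @return A [FeatureBlock] with modality `tma`.
#' @export
encodeTMA <- function(record) {
  vals <- vapply(.TMA_KEYS, function(k) {
    v <- record$tma_density[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  if (any(!is.na(vals) & vals < 0)) {
    stop("validation error: negative TMA density")
  }
  new("FeatureBlock", modality = "tma", names = paste0("tma.", .TMA_KEYS),
      values = unname(vals), kind = rep("numeric", 4L))
}

# Pre-expansion raw feature matrix (patients x features) with NA for
# missing, plus per-column modality/kind metadata.
.rawFeatureMatrix <- function(cohort, schema, vocabulary) {
  recs <- records(cohort)
  n <- length(recs)
  blocks <- lapply(recs, function(r) {
    list(encodeStructured(r, schema), encodeBlood(r, schema$bloodPanel),
         encodeTMA(r))
  })
  clin <- t(vapply(blocks, function(b) b[[1]]@values,
                   numeric(length(schema$structured))))
  blood <- t(vapply(blocks, function(b) b[[2]]@values,
                    numeric(length(schema$bloodPanel))))
  tma <- t(vapply(blocks, function(b) b[[3]]@values, numeric(4L)))
  icd <- icdCounts(cohort, vocabulary)
  b1 <- blocks[[1]]
  x <- cbind(clin, blood, icd, tma)
  colnames(x) <- c(b1[[1]]@names, b1[[2]]@names,
                   if (length(vocabulary)) paste0("icd.", vocabulary),
                   b1[[3]]@names)
  rownames(x) <- patientIds(cohort)
  meta <- data.frame(
    name = colnames(x),
    modality = c(rep("clinical_pathological", ncol(clin)),
                 rep("blood", ncol(blood)), rep("icd", ncol(icd)),
                 rep("tma", ncol(tma))),
    kind = c(b1[[1]]@kind, b1[[2]]@kind, rep("bow", ncol(icd)), b1[[3]]@kind),
    stringsAsFactors = FALSE
  )
  list(x = x, meta = meta)
}

# Completeness flags, decided BEFORE imputation: the structured core must
# be there (it always is for validated records), and the blood, ICD and
# TMA modalities must each be represented by at least one observed value.
.completenessFlags <- function(cohort, schema) {
  vapply(records(cohort), function(r) {
    bloodOk <- any(vapply(schema$bloodPanel,
                          function(p) !is.null(r$blood[[p]]), logical(1)))
    tmaOk <- any(vapply(.TMA_KEYS,
                        function(k) !is.null(r$tma_density[[k]]), logical(1)))
    icdOk <- !is.null(r$icd_codes) && length(r$icd_codes) > 0L
    stagedOk <- !is.null(r$pt_stage) && !is.null(r$pn_stage)
    bloodOk && tmaOk && icdOk && stagedOk
  }, logical(1))
}

#' Fit the data-dependent encoding state on a cohort
#'
#' Computes the ICD vocabulary, the observed levels of each categorical
#' feature, per-feature imputation values (mode for binary/categorical,
#' mean for numeric/ordinal) and the z-score statistics of the ordinal
#' and numeric columns. Fit it on training patients only to obtain a
#' leakage-free encoder for held-out data.
#'
#' @param cohort A [Cohort].
#' @param schema Encoding schema.
#' @return A [Vectorizer].
#' @export
fitVectorizer <- function(cohort, schema = defaultSchema()) {
  stopifnot(is(cohort, "Cohort"), length(cohort) >= 1L)
  vocabulary <- encodeICD(cohort, schema$minSupport)$vocabulary
  raw <- .rawFeatureMatrix(cohort, schema, vocabulary)
  x <- raw$x
  meta <- raw$meta
  levelsList <- list()
  imputeValues <- list()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    kind <- meta$kind[j]
    if (kind %in% c("binary", "categorical_label")) {
      imputeValues[[meta$name[j]]] <- .modeValue(v)
      if (kind == "categorical_label") {
        levelsList[[meta$name[j]]] <- sort(unique(v[!is.na(v)]))
      }
    } else {
      m <- mean(v, na.rm = TRUE)
      imputeValues[[meta$name[j]]] <- if (is.nan(m)) 0 else m
    }
  }
  # scaling statistics on imputed, pre-expansion columns
  center <- numeric(0)
  scl <- numeric(0)
  for (j in which(meta$kind %in% c("ordinal", "numeric"))) {
    v <- x[, j]
    v[is.na(v)] <- imputeValues[[meta$name[j]]]
    mu <- mean(v)
    sdev <- sd(v)
    center[meta$name[j]] <- mu
    scl[meta$name[j]] <- if (is.na(sdev) || sdev == 0) 1 else sdev
  }
  new("Vectorizer", schema = schema, vocabulary = vocabulary,
      levels = levelsList, imputeValues = imputeValues,
      center = center, scale = scl)
}

#' Apply a fitted Vectorizer to a cohort
#'
#' Produces the multimodal patient vectors: blocks concatenated in fixed
#' modality order (clinical/pathological, blood, ICD, TMA), missing
#' values imputed with the fitted statistics, categorical labels expanded
#' one-hot over the fitted observed levels (pure indicators, no dropped
#' reference level; unseen levels map to all-zero indicators), ordinal
#' and numeric columns z-scored with the fitted statistics.
#'
#' @param vectorizer A fitted [Vectorizer].
#' @param cohort A [Cohort].
#' @return A [PatientVectors] object.
#' @export
applyVectorizer <- function(vectorizer, cohort) {
  stopifnot(is(vectorizer, "Vectorizer"), is(cohort, "Cohort"))
  schema <- vectorizer@schema
  raw <- .rawFeatureMatrix(cohort, schema, vectorizer@vocabulary)
  x <- raw$x
  meta <- raw$meta
  complete <- .completenessFlags(cohort, schema)
  preExpansionDim <- ncol(x)

  cols <- list()
  colMeta <- list()
  for (j in seq_len(ncol(x))) {
    nm <- meta$name[j]
    kind <- meta$kind[j]
    modality <- meta$modality[j]
    v <- x[, j]
    imp <- vectorizer@imputeValues[[nm]]
    if (!is.null(imp)) v[is.na(v)] <- imp
    if (kind == "categorical_label") {
      levs <- vectorizer@levels[[nm]]
      schemaLevels <- schema$structured[[nm]]$levels
      for (lv in levs) {
        cols[[length(cols) + 1L]] <- as.numeric(v == lv)
        colMeta[[length(colMeta) + 1L]] <-
          c(paste0(nm, "=", schemaLevels[lv]), modality, kind, nm)
      }
    } else {
      if (kind %in% c("ordinal", "numeric")) {
        v <- (v - vectorizer@center[[nm]]) / vectorizer@scale[[nm]]
      }
      cols[[length(cols) + 1L]] <- v
      colMeta[[length(colMeta) + 1L]] <- c(nm, modality, kind, nm)
    }
  }
  mat <- do.call(cbind, cols)
  cm <- do.call(rbind, colMeta)
  colnames(mat) <- make.unique(cm[, 1])
  rownames(mat) <- patientIds(cohort)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(vectors = t(mat)),
    rowData = S4Vectors::DataFrame(name = cm[, 1], modality = cm[, 2],
                                   kind = cm[, 3], sourceFeature = cm[, 4]),
    colData = S4Vectors::DataFrame(patient_id = patientIds(cohort),
                                   complete = complete,
                                   row.names = patientIds(cohort)),
    metadata = list(preExpansionDim = preExpansionDim,
                    vocabulary = vectorizer@vocabulary)
  )
  new("PatientVectors", se)
}

#' Assemble multimodal patient vectors for a whole cohort
#'
#' Cohort-level encoding (vocabulary, levels, imputation and scaling fit
#' on all patients) as used for visualization and for the genetic
#' algorithm split. For model evaluation, the encoder is instead fit on
#' training patients only inside [fitPredict()].
#'
#' Completeness flags are recorded before any imputation. Zero-variance
#' numeric columns are left at 0 after centering. The pre-expansion
#' dimension is reported in `metadata()$preExpansionDim`.
#'
#' @param cohort A [Cohort].
#' @param schema Encoding schema, see [defaultSchema()].
#' @return A [PatientVectors] object.
#' @examples
#' cohort <- generateCohort(simConfig(nPatients = 30, seed = 1))
#' vs <- assembleVectors(cohort)
#' dim(vectorMatrix(vs))
#' @export
assembleVectors <- function(cohort, schema = defaultSchema()) {
  applyVectorizer(fitVectorizer(cohort, schema), cohort)
}

#' Project patient vectors to two dimensions
#'
#' Classical metric multidimensional scaling on the pairwise cosine
#' distance matrix, followed by min-max rescaling of each axis to
#' `[0, 1]`. Intended for visual exploration of the cohort structure.
#'
#' @param vectors A [PatientVectors] object or numeric matrix
#'   (patients x features) with at least 3 rows.
#' @param seed Integer seed (kept for interface stability; the embedding
#'   itself is deterministic).
#' @return Numeric matrix (patients x 2) with columns `dim1`, `dim2`,
#'   each spanning exactly `[0, 1]`.
#' @export
project2D <- function(vectors, seed = 1L) {
  x <- if (is(vectors, "PatientVectors")) vectorMatrix(vectors) else vectors
  if (nrow(x) < 3L) stop("argument error: projection needs at least 3 patients")
  set.seed(seed)
  d <- 1 - .cosineSimMatrix(x)
  d[d < 0] <- 0
  coords <- stats::cmdscale(stats::as.dist(d), k = 2)
  if (ncol(coords) < 2L) coords <- cbind(coords, 0)
  rescale <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  out <- apply(coords, 2, rescale)
  dimnames(out) <- list(rownames(x), c("dim1", "dim2"))
  out
}
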