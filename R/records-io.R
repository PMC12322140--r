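# JSON data model for patient-centered cohort records.
#
# One JSON array per cohort, one object per patient, keys in the fixed
# order of .RECORD_FIELDS. Missing values are encoded as JSON null; an
# absent key is equivalent to null. All event fields are integer day
# counts with day 0 = initial diagnosis. A machine-readable data
# dictionary ships in inst/extdata/cohort-schema.json.

# Validate one record; returns character vector of problems (empty = ok).
.validateRecord <- function(rec) {
  probs <- character(0)
  bad <- function(msg) probs <<- c(probs, msg)

  id <- rec[["patient_id"]]
  if (!.isScalarString(id) || !grepl("^[0-9]+$", id)) {
    bad("patient_id must be a zero-padded numeric string")
  }

  chk_cat <- function(field, levels, allowMissing = FALSE) {
    v <- .fieldOrNA(rec, field)
    if (length(v) == 1L && is.na(v)) {
      if (!allowMissing) bad(sprintf("%s is required", field))
    } else if (!.isScalarString(v) || !(v %in% levels)) {
      bad(sprintf("%s: value %s outside domain {%s}", field,
                  deparse(v), paste(levels, collapse = ", ")))
    }
  }
  chk_cat("sex", .SEX_LEVELS)
  chk_cat("smoking_status", .SMOKING_LEVELS)
  chk_cat("primary_site", .SITE_LEVELS)
  chk_cat("grading", .GRADING_LEVELS, allowMissing = TRUE)
  chk_cat("pt_stage", names(.PT_TABLE), allowMissing = TRUE)
  chk_cat("pn_stage", names(.PN_TABLE), allowMissing = TRUE)

  age <- .fieldOrNA(rec, "age_at_diagnosis")
  if (length(age) != 1L || is.na(age) || !is.numeric(age) || age < 0 ||
      age != round(age)) {
    bad("age_at_diagnosis must be a non-negative integer")
  }

  for (f in .FLAG_FIELDS) {
    v <- .fieldOrNA(rec, f)
    if (!(length(v) == 1L && (is.na(v) || is.logical(v)))) {
      bad(sprintf("%s must be true, false or null", f))
    }
  }

  blood <- rec[["blood"]]
  if (!is.null(blood)) {
    if (!is.list(blood)) {
      bad("blood must be a map parameter -> {value, unit, group}")
    } else if (length(blood)) {
      if (is.null(names(blood)) || any(names(blood) == "")) {
        bad("blood entries must be named by parameter")
      }
      for (p in names(blood)) {
        e <- blood[[p]]
        if (!is.list(e) || !.isScalarNumber(e[["value"]]) ||
            !.isScalarString(e[["unit"]]) || !.isScalarString(e[["group"]])) {
          bad(sprintf("blood parameter %s needs finite value, unit, group", p))
        }
      }
    }
  }

  icd <- rec[["icd_codes"]]
  if (!is.null(icd) && length(icd)) {
    codes <- unlist(icd, use.names = FALSE)
    if (!is.character(codes) || anyNA(codes)) bad("icd_codes must be strings")
  }

  tma <- rec[["tma_density"]]
  if (!is.null(tma) && length(tma)) {
    if (!all(names(tma) %in% .TMA_KEYS)) {
      bad(sprintf("tma_density keys must be among {%s}",
                  paste(.TMA_KEYS, collapse = ", ")))
    }
    for (k in names(tma)) {
      v <- tma[[k]]
      if (!is.null(v) && (!.isScalarNumber(v) || v < 0)) {
        bad(sprintf("tma_density %s must be a non-negative density", k))
      }
    }
  }

  chk_day <- function(field, required = FALSE) {
    v <- .fieldOrNA(rec, field)
    if (length(v) == 1L && is.na(v)) {
      if (required) bad(sprintf("%s is required", field))
    } else if (!.isScalarNumber(v) || v < 0 || v != round(v)) {
      bad(sprintf("%s must be a non-negative integer day count", field))
    }
  }
  chk_day("recurrence_days")
  chk_day("death_days")
  chk_day("followup_days", required = TRUE)

  dts <- .fieldOrNA(rec, "death_tumor_specific")
  if (!(length(dts) == 1L && (is.na(dts) || is.logical(dts)))) {
    bad("death_tumor_specific must be true, false or null")
  }

  probs
}

# Canonical in-memory form: fixed field order, typed atoms, NULL for
# missing. Unknown extra fields are preserved after the known ones.
.canonicalRecord <- function(rec) {
  out <- list()
  for (f in .RECORD_FIELDS) {
    v <- rec[[f]]
    if (is.null(v) || (length(v) == 1L && !is.list(v) && is.na(v))) {
      out[f] <- list(NULL)
      next
    }
    if (f %in% c("age_at_diagnosis", "recurrence_days", "death_days",
                 "followup_days")) {
      v <- as.integer(v)
    } else if (f == "patient_id") {
      v <- as.character(v)
    } else if (f == "icd_codes") {
      v <- as.character(unlist(v, use.names = FALSE))
    } else if (f == "blood") {
      v <- lapply(v, function(e) list(value = as.numeric(e[["value"]]),
                                      unit = as.character(e[["unit"]]),
                                      group = as.character(e[["group"]])))
      v <- v[sort(names(v))]
    } else if (f == "tma_density") {
      v <- v[intersect(.TMA_KEYS, names(v))]
      v <- lapply(v, function(e) if (is.null(e)) NULL else as.numeric(e))
      if (length(v) == 0L) { out[f] <- list(NULL); next }
    }
    out[[f]] <- v
  }
  extra <- setdiff(names(rec), .RECORD_FIELDS)
  for (f in extra) out[[f]] <- rec[[f]]
  out
}

#' Construct a validated Cohort
#'
#' Records are canonicalized (fixed field order, typed values, `NULL` for
#' missing) and sorted by `patient_id`; validation is run on construction.
#'
#' @param records List of patient records (named lists).
#' @param schemaVersion Schema version string.
#' @return A [Cohort] object.
#' @examples
#' newCohort(list())
#' @export
newCohort <- function(records, schemaVersion = .SCHEMA_VERSION) {
  records <- lapply(records, .canonicalRecord)
  ids <- vapply(records, function(r) as.character(r[["patient_id"]]), character(1))
  records <- records[order(ids)]
  new("Cohort", records = records, schemaVersion = schemaVersion)
}

#' Read a cohort from a JSON file
#'
#' Expects a UTF-8 JSON array with one object per patient. Unknown extra
#' fields are preserved but ignored downstream. Records are sorted by
#' `patient_id` and validated; a domain violation raises an error naming
#' the patient and field.
#'
#' @param path Path to a JSON file.
#' @return A validated [Cohort].
#' @seealso [writeCohort()]
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parsed <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("JSON parse failure in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.list(parsed) || (length(parsed) && !is.null(names(parsed)))) {
    stop("expected a JSON array of patient record objects")
  }
  recs <- lapply(parsed, function(r) {
    # flatten scalar JSON values parsed as length-1 lists
    for (f in setdiff(names(r), c("blood", "tma_density", "icd_codes"))) {
      if (is.list(r[[f]]) && length(r[[f]]) == 1L) r[[f]] <- r[[f]][[1L]]
    }
    if (!is.null(r[["tma_density"]])) {
      r[["tma_density"]] <- lapply(r[["tma_density"]], function(v) {
        if (is.list(v)) v[[1L]] else v
      })
    }
    r
  })
  newCohort(recs)
}

#' Write a cohort to a JSON file
#'
#' Emits a JSON array with one object per patient, keys in the documented
#' fixed order, missing values as `null`. Output is byte-identical across
#' runs for identical input.
#'
#' @param cohort A validated [Cohort].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "Cohort"))
  validObject(cohort)
  txt <- .cohortToJSON(cohort)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}

.cohortToJSON <- function(cohort) {
  if (length(cohort) == 0L) return("[]\n")
  objs <- vapply(cohort@records, function(rec) {
    rec <- .canonicalRecord(rec)
    # keep icd_codes an array even when it has a single element
    if (!is.null(rec$icd_codes)) rec$icd_codes <- I(as.character(rec$icd_codes))
    body <- jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                             na = "null", digits = NA, pretty = FALSE)
    as.character(body)
  }, character(1))
  paste0("[\n", paste(objs, collapse = ",\n"), "\n]\n")
}

#' Path to the shipped data dictionary
#'
#' Returns the location of the machine-readable schema (field, type,
#' possible values) describing the cohort JSON format.
#'
#' @return File path of `cohort-schema.json`.
#' @export
cohortSchemaPath <- function() {
  system.file("extdata", "cohort-schema.json", package = "oncofusion",
              mustWork = TRUE)
}
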