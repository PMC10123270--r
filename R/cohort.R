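# Cohort table schema and validation.
#
# A cohort is a plain data.frame, one row per eye, with the measured columns
#   subject_id, eye (OD/OS), age (years), gender (female/male),
#   ser_d (D), ssi (unitless), cct_um (um), cr_mm (mm), al_mm (mm)
# and, once compute_derived() has run, the derived columns
#   al_morgan_mm, al_emmetropia_mm, delta_al_mm.

.measured_cols <- c("subject_id", "eye", "age", "gender",
                    "ser_d", "ssi", "cct_um", "cr_mm", "al_mm")
.derived_cols <- c("al_morgan_mm", "al_emmetropia_mm", "delta_al_mm")

# Physiological guard ranges (open intervals); values outside are treated as
# data errors, not clinical findings.
.guards <- list(
  cr_mm  = c(5, 12),
  al_mm  = c(15, 40),
  ssi    = c(0.2, 2.5),
  cct_um = c(300, 800)
)

#' Empty cohort table with the full column schema
#'
#' @param derived include the derived columns (default `TRUE`).
#' @return A zero-row data.frame with the cohort schema.
#' @export
empty_cohort <- function(derived = TRUE) {
  out <- data.frame(
    subject_id = character(0), eye = character(0), age = numeric(0),
    gender = character(0), ser_d = numeric(0), ssi = numeric(0),
    cct_um = numeric(0), cr_mm = numeric(0), al_mm = numeric(0),
    stringsAsFactors = FALSE
  )
  if (derived) for (cl in .derived_cols) out[[cl]] <- numeric(0)
  out
}

#' Validate a cohort table
#'
#' Checks column presence, eye and gender codes, and finiteness of the
#' measured numeric columns. Called by every pipeline entry point.
#'
#' @param table a cohort data.frame.
#' @param require_derived also require the derived columns.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(table, require_derived = FALSE) {
  if (!is.data.frame(table)) stop("cohort must be a data.frame", call. = FALSE)
  need <- .measured_cols
  if (require_derived) need <- c(need, .derived_cols)
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0) return(invisible(table))
  bad_eye <- !table$eye %in% c("OD", "OS")
  if (any(bad_eye)) {
    stop("unknown eye code '", table$eye[bad_eye][1L], "' at row ",
         which(bad_eye)[1L], call. = FALSE)
  }
  bad_gender <- !table$gender %in% c("female", "male")
  if (any(bad_gender)) {
    stop("unknown gender code '", table$gender[bad_gender][1L], "' at row ",
         which(bad_gender)[1L], call. = FALSE)
  }
  for (cl in c("age", "ser_d", "ssi", "cct_um", "cr_mm", "al_mm")) {
    if (!is.numeric(table[[cl]]) || anyNA(table[[cl]]) ||
        !all(is.finite(table[[cl]]))) {
      stop("column '", cl, "' must be finite numeric with no missing values",
           call. = FALSE)
    }
  }
  invisible(table)
}

# Logical vector: rows passing the physiological guards.
guards_ok <- function(table) {
  ok <- rep(TRUE, nrow(table))
  for (cl in names(.guards)) {
    rng <- .guards[[cl]]
    v <- table[[cl]]
    ok <- ok & is.finite(v) & v > rng[1] & v < rng[2]
  }
  ok
}

#' Write a cohort table to CSV
#'
#' One row per eye, UTF-8, fixed header names; derived columns are written
#' when present. Numeric values keep full double precision so that a
#' write/read round trip is lossless to well below 1e-9.
#'
#' @param table a cohort data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  validate_cohort(table)
  keep <- intersect(c(.measured_cols, .derived_cols), names(table))
  utils::write.csv(table[keep], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Values pass through verbatim: no sign conventions or units are guessed or
#' corrected. Malformed rows and unknown codes are reported with their file
#' line number (header is line 1).
#'
#' @param path CSV file path.
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(.measured_cols, names(tab))
  if (length(missing)) {
    stop("cohort file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$subject_id <- as.character(tab$subject_id)
  if (nrow(tab)) {
    bad_eye <- !tab$eye %in% c("OD", "OS")
    if (any(bad_eye)) {
      stop("line ", which(bad_eye)[1L] + 1L, ": unknown eye code '",
           tab$eye[bad_eye][1L], "'", call. = FALSE)
    }
    bad_gender <- !tab$gender %in% c("female", "male")
    if (any(bad_gender)) {
      stop("line ", which(bad_gender)[1L] + 1L, ": unknown gender code '",
           tab$gender[bad_gender][1L], "'", call. = FALSE)
    }
    for (cl in c("age", "ser_d", "ssi", "cct_um", "cr_mm", "al_mm")) {
      v <- tab[[cl]]
      if (!is.numeric(v) || anyNA(v)) {
        bad <- if (is.numeric(v)) which(is.na(v))[1L] else 1L
        stop("line ", bad + 1L, ": column '", cl,
             "' is not a finite number", call. = FALSE)
      }
    }
  }
  tab
}
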