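# Record-level exclusion filtering. The clinical eligibility rules are
# re-expressed as data-validation rules so arbitrary input files can be
# screened: high astigmatism, contact-lens wear, corneal disease, prior eye
# surgery, a failed measurement-quality flag, and physiologically
# out-of-range values.

#' Apply eligibility and range exclusions to a cohort
#'
#' Removes records meeting any exclusion rule and reports per-rule counts.
#' The flag columns are optional: `astigmatism_d` (numeric, excluded at
#' 3 D or more), `contact_lens`, `corneal_disease`, `prior_surgery`
#' (logical, excluded when `TRUE`) and `quality_ok` (logical, excluded when
#' `FALSE`). Records lacking an optional column are retained for that rule,
#' with a warning. Physiological-guard violations (corneal radius outside
#' 5-12 mm, axial length outside 15-40 mm, SSI outside 0.2-2.5, CCT outside
#' 300-800 um) are always excluded. A record can violate several rules; the
#' per-rule counts count each violation, while the excluded set is their
#' union, so excluded + retained always equals the input count. The filter
#' is idempotent.
#'
#' @param table a cohort data.frame (measured columns required; flag columns
#'   optional).
#' @return A list with `cohort` (retained records) and `report`
#'   (class `exclusion_report`).
#' @export
apply_exclusions <- function(table) {
  validate_cohort(table)
  n <- nrow(table)
  rules <- list(
    astigmatism = list(col = "astigmatism_d",
                       fn = function(v) is.finite(v) & v >= 3),
    contact_lens = list(col = "contact_lens", fn = function(v) isTRUE_vec(v)),
    corneal_disease = list(col = "corneal_disease",
                           fn = function(v) isTRUE_vec(v)),
    prior_surgery = list(col = "prior_surgery",
                         fn = function(v) isTRUE_vec(v)),
    failed_quality = list(col = "quality_ok",
                          fn = function(v) !is.na(v) & !v)
  )
  counts <- integer(0)
  excluded <- rep(FALSE, n)
  absent <- setdiff(vapply(rules, `[[`, character(1), "col"), names(table))
  if (length(absent)) {
    warning("optional exclusion column(s) not present, rule(s) skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  for (nm in names(rules)) {
    rule <- rules[[nm]]
    if (!rule$col %in% names(table)) {
      counts[nm] <- 0L
      next
    }
    hit <- rule$fn(table[[rule$col]])
    counts[nm] <- sum(hit)
    excluded <- excluded | hit
  }
  out_of_range <- if (n) !guards_ok(table) else logical(0)
  counts["out_of_range"] <- sum(out_of_range)
  excluded <- excluded | out_of_range

  report <- structure(list(
    n_input = n, n_excluded = sum(excluded), n_retained = sum(!excluded),
    counts = counts,
    excluded_ids = table$subject_id[excluded]
  ), class = "exclusion_report")
  list(cohort = table[!excluded, , drop = FALSE], report = report)
}

isTRUE_vec <- function(v) !is.na(v) & as.logical(v)

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report: %d input, %d excluded, %d retained\n",
              x$n_input, x$n_excluded, x$n_retained))
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
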