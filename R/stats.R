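# Statistical pipeline: derived variables, correlation, Bland-Altman
# agreement, simple and covariate-adjusted linear models, subgroup and group
# summaries, descriptive tables.

#' Populate the derived model columns of a cohort
#'
#' Adds `al_morgan_mm` (Morgan estimate from corneal radius and refraction),
#' `al_emmetropia_mm` (emmetropic length from corneal radius) and
#' `delta_al_mm` (measured minus emmetropic length) to every record.
#' Recomputation is idempotent.
#'
#' @param table a cohort data.frame with measured columns.
#' @param constants a [morgan_constants()] object.
#' @return The table with the three derived columns populated.
#' @export
compute_derived <- function(table, constants = morgan_constants()) {
  validate_cohort(table)
  if (nrow(table) == 0) {
    for (cl in .derived_cols) table[[cl]] <- numeric(0)
    return(table)
  }
  denom <- constants$a / table$cr_mm + constants$b * table$ser_d + constants$c
  bad <- table$cr_mm <= 0 | denom <= 0
  if (any(bad)) {
    stop("Morgan model undefined for record(s): ",
         paste(table$subject_id[bad], collapse = ", "), call. = FALSE)
  }
  table$al_morgan_mm <- al_morgan(table$cr_mm, table$ser_d, constants)
  table$al_emmetropia_mm <- al_emmetropia(table$cr_mm, constants)
  table$delta_al_mm <- delta_al(table$al_mm, table$al_emmetropia_mm)
  table
}

#' Pearson correlation with its t statistic
#'
#' Product-moment correlation together with the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and the two-sided p-value from the
#' t distribution on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, neither constant.
#' @return An object of class `cor_t` with fields `r`, `t`, `df`, `p`, `n`.
#' @examples
#' pearson_with_t(1:10, (1:10)^2)
#' @export
pearson_with_t <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(r = r, t = t, df = df, p = p, n = n), class = "cor_t")
}

#' @export
print.cor_t <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.3f, t = %.2f (df = %d), p %s\n",
              x$r, x$t, x$df, format_p(x$p)))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `measured - estimate`; the direction convention
#' is recorded in the result. Limits of agreement are
#' `bias +/- multiplier * sd_diff` with the sample (n-1) SD.
#'
#' @param measured,estimate numeric vectors of equal length, n >= 2 (mm).
#' @param multiplier half-width of the limits in SD units; default 1.96.
#' @return An object of class `bland_altman` with fields `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `multiplier`, `n`, `direction`.
#' @examples
#' bland_altman(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.1))
#' @export
bland_altman <- function(measured, estimate, multiplier = 1.96) {
  if (length(measured) != length(estimate)) {
    stop("measured and estimate must have equal length", call. = FALSE)
  }
  if (length(measured) < 2) {
    stop("need at least 2 paired observations", call. = FALSE)
  }
  d <- measured - estimate
  if (!all(is.finite(d))) stop("inputs must be finite", call. = FALSE)
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - multiplier * sd_diff,
    loa_high = bias + multiplier * sd_diff,
    multiplier = multiplier, n = length(d),
    direction = "measured - estimate"
  ), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (difference = %s, n = %d)\n",
              x$direction, x$n))
  cat(sprintf("  bias %.3f mm, SD %.3f mm, %g%% LoA [%.3f, %.3f] mm\n",
              x$bias, x$sd_diff,
              round(100 * (2 * stats::pnorm(x$multiplier) - 1)),
              x$loa_low, x$loa_high))
  invisible(x)
}

# Significance stars matching the conventional regression-table legend.
signif_stars <- function(p) {
  as.character(cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                   labels = c("***", "**", "*", "")))
}

format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("= %.3f", p))
}

# Build the modelling frame: outcome plus predictors, with gender expanded
# to a male indicator (male = 1, female = 0).
model_frame <- function(table, outcome, predictors) {
  validate_cohort(table, require_derived = outcome %in% .derived_cols ||
                    any(predictors %in% .derived_cols))
  cols <- c(outcome, setdiff(predictors, "gender"))
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("column(s) not present in cohort: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  d <- table[, cols, drop = FALSE]
  if ("gender" %in% predictors) {
    d$male <- as.integer(table$gender == "male")
  }
  d
}

#' Fit an ordinary least-squares linear model on a cohort
#'
#' Thin wrapper around [stats::lm()] that returns a tidy coefficient table
#' with standard errors, t-based 95% confidence intervals
#' (`estimate +/- t_crit * SE`, df = n - p), two-sided p-values and
#' significance stars (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05).
#' `"gender"` among the predictors is coded as a male indicator (male = 1).
#'
#' @param table a cohort data.frame.
#' @param outcome outcome column name.
#' @param predictors character vector of predictor column names.
#' @param label optional model label carried into reports.
#' @param conf_level confidence level for the intervals; default 0.95.
#' @return An object of class `biometry_fit`: a list with `label`, `outcome`,
#'   `coefficients` (data.frame term/estimate/se/ci_low/ci_high/p/stars),
#'   `n`, `r_squared`, `sigma`, and the underlying `lm` fit.
#' @export
fit_linear_model <- function(table, outcome, predictors,
                             label = outcome, conf_level = 0.95) {
  d <- model_frame(table, outcome, predictors)
  p_terms <- setdiff(names(d), outcome)
  if (nrow(d) <= length(p_terms) + 1L) {
    stop("too few records (", nrow(d), ") to fit ", length(p_terms) + 1L,
         " coefficients", call. = FALSE)
  }
  form <- stats::reformulate(p_terms, response = outcome)
  X <- stats::model.matrix(form, d)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(form, data = d)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, "Estimate"],
    se = sm$coefficients[, "Std. Error"],
    ci_low = ci[, 1L], ci_high = ci[, 2L],
    p = sm$coefficients[, "Pr(>|t|)"],
    stars = signif_stars(sm$coefficients[, "Pr(>|t|)"]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(
    label = label, outcome = outcome, coefficients = coefs,
    n = nrow(d), r_squared = sm$r.squared, sigma = sm$sigma,
    conf_level = conf_level, fit = fit
  ), class = "biometry_fit")
}

#' @export
print.biometry_fit <- function(x, ...) {
  cat(sprintf("Linear model %s: %s ~ %s  (n = %d, R^2 = %.3f)\n",
              x$label, x$outcome,
              paste(setdiff(x$coefficients$term, "(Intercept)"),
                    collapse = " + "),
              x$n, x$r_squared))
  tab <- x$coefficients
  cat(sprintf("  %-14s %9s %8s  [%s CI]  %s\n", "term", "estimate", "SE",
              paste0(100 * x$conf_level, "%"), "p"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %9.3f %8.3f  [%7.3f, %7.3f]  %s %s\n",
                tab$term[i], tab$estimate[i], tab$se[i],
                tab$ci_low[i], tab$ci_high[i],
                format_p(tab$p[i]), tab$stars[i]))
  }
  invisible(x)
}

#' Covariate-adjusted models of the three biometric outcomes
#'
#' Fits the same design (SSI + age + gender + CCT) to three outcomes on one
#' cohort: model 1, measured axial length; model 2, emmetropic axial length;
#' model 3, axial increment. Because the outcome of model 1 is the sum of
#' the other two and the design matrix is identical, model 1 coefficients
#' equal the termwise sum of models 2 and 3 exactly.
#'
#' @param table a cohort with derived columns (see [compute_derived()]).
#' @return A named list of three `biometry_fit` objects
#'   (`model1`, `model2`, `model3`), class `adjusted_models`.
#' @export
run_adjusted_models <- function(table) {
  preds <- c("ssi", "age", "gender", "cct_um")
  structure(list(
    model1 = fit_linear_model(table, "al_mm", preds, label = "Model 1 (AL)"),
    model2 = fit_linear_model(table, "al_emmetropia_mm", preds,
                              label = "Model 2 (ALemmetropia)"),
    model3 = fit_linear_model(table, "delta_al_mm", preds,
                              label = "Model 3 (deltaAL)")
  ), class = "adjusted_models")
}

#' @export
print.adjusted_models <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}

#' Axial-increment model restricted to long eyes
#'
#' Refits the adjusted axial-increment model (outcome `delta_al_mm`,
#' covariates SSI, age, gender, CCT) on the subgroup with measured axial
#' length at or above `al_threshold` (inclusive).
#'
#' @param table a cohort with derived columns.
#' @param al_threshold axial-length cut in mm; default 26.
#' @return A `biometry_fit` for the subgroup.
#' @export
subgroup_model <- function(table, al_threshold = 26.0) {
  validate_cohort(table, require_derived = TRUE)
  sub <- table[table$al_mm >= al_threshold, , drop = FALSE]
  n_terms <- 5L  # intercept + ssi + age + male + cct
  if (nrow(sub) <= n_terms + 1L) {
    stop("subgroup AL >= ", al_threshold, " mm has only ", nrow(sub),
         " record(s); too few to fit the adjusted model", call. = FALSE)
  }
  fit_linear_model(sub, "delta_al_mm", c("ssi", "age", "gender", "cct_um"),
                   label = sprintf("Model 3, AL >= %.4g mm", al_threshold))
}

#' Group means of the axial decomposition
#'
#' Mean emmetropic axial length and mean axial increment within groups
#' defined by two splits: measured axial length below vs at/above
#' `al_threshold` mm, and refraction above vs at/below `ser_threshold` D
#' (the severe-myopia group includes the boundary value). Empty groups are
#' simply absent from the output.
#'
#' @param table a cohort with derived columns.
#' @param al_threshold axial-length split, mm; default 26.
#' @param ser_threshold refraction split, D; default -6.
#' @return A data.frame with columns `split`, `group`, `n`,
#'   `mean_al_emmetropia`, `mean_delta_al`.
#' @export
group_summary <- function(table, al_threshold = 26.0, ser_threshold = -6.0) {
  validate_cohort(table, require_derived = TRUE)
  one_split <- function(split, member) {
    out <- NULL
    for (g in names(member)) {
      idx <- member[[g]]
      if (!any(idx)) next
      out <- rbind(out, data.frame(
        split = split, group = g, n = sum(idx),
        mean_al_emmetropia = mean(table$al_emmetropia_mm[idx]),
        mean_delta_al = mean(table$delta_al_mm[idx]),
        stringsAsFactors = FALSE
      ))
    }
    out
  }
  al_groups <- list(
    "AL < 26 mm" = table$al_mm < al_threshold,
    "AL >= 26 mm" = table$al_mm >= al_threshold
  )
  names(al_groups) <- c(sprintf("AL < %.4g mm", al_threshold),
                        sprintf("AL >= %.4g mm", al_threshold))
  ser_groups <- list(table$ser_d > ser_threshold,
                     table$ser_d <= ser_threshold)
  names(ser_groups) <- c(sprintf("SER > %.2f D", ser_threshold),
                         sprintf("SER <= %.2f D", ser_threshold))
  rbind(one_split("AL", al_groups), one_split("SER", ser_groups))
}

#' Descriptive summary of a cohort
#'
#' Mean (SD) for the continuous variables and n (%) for gender, with
#' conventional clinical-table rounding: whole numbers for age and CCT, two
#' decimals elsewhere, whole-percent gender shares. With a single record the
#' SD is reported as 0.
#'
#' @param table a cohort; derived columns are summarized when present.
#' @return A data.frame with columns `characteristic`, `mean`, `sd`,
#'   `formatted` (gender rows carry count/percentage instead of mean/SD).
#' @export
descriptive_table <- function(table) {
  validate_cohort(table)
  if (nrow(table) == 0) stop("cohort is empty", call. = FALSE)
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  specs <- list(
    c("Age, years", "age", "0"),
    c("SER, diopter", "ser_d", "2"),
    c("SSI", "ssi", "2"),
    c("CCT, um", "cct_um", "0"),
    c("CR, mm", "cr_mm", "2"),
    c("AL, mm", "al_mm", "2"),
    c("ALMorgan, mm", "al_morgan_mm", "2"),
    c("ALemmetropia, mm", "al_emmetropia_mm", "2"),
    c("deltaAL, mm", "delta_al_mm", "2")
  )
  rows <- list()
  for (s in specs) {
    if (!s[2] %in% names(table)) next
    v <- table[[s[2]]]
    dg <- as.integer(s[3])
    fmt <- paste0("%.", dg, "f (%.", dg, "f)")
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = s[1], mean = mean(v), sd = sd0(v),
      formatted = sprintf(fmt, mean(v), sd0(v)), stringsAsFactors = FALSE
    )
  }
  n <- nrow(table)
  for (g in c("female", "male")) {
    cnt <- sum(table$gender == g)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0("Gender: ", g), mean = NA_real_, sd = NA_real_,
      formatted = sprintf("%d (%.0f%%)", cnt, 100 * cnt / n),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  out
}
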