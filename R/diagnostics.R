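# Regression assumption checks. The choice of concrete tests is an
# implementation decision of this package: Shapiro-Wilk (Anderson-Darling
# beyond n = 5000) for residual normality, the studentized Breusch-Pagan
# test for homogeneity of variance, the Durbin-Watson statistic for
# first-order residual autocorrelation, and an F-test on quadratic
# augmentation terms for linearity.

#' Assumption diagnostics for a fitted linear model
#'
#' Runs four checks on a [fit_linear_model()] result and flags each at the
#' given significance level: residual normality, heteroscedasticity,
#' first-order residual autocorrelation, and linearity (quadratic terms in
#' the continuous predictors should not improve the fit). A check that
#' cannot be computed — residuals numerically degenerate, sample too small,
#' no continuous predictors — is reported as not computed rather than
#' failing.
#'
#' @param fit a `biometry_fit` object.
#' @param alpha flag threshold for the test p-values; default 0.05.
#' @return An object of class `regression_diagnostics`: a named list of
#'   checks, each with `test`, `statistic`, `p_value`, `pass`, `computed`.
#' @export
run_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "biometry_fit"))
  res <- stats::residuals(fit$fit)
  n <- length(res)
  degenerate <- n < 3 || stats::sd(res) < 1e-10

  not_computed <- function(test, reason) {
    list(test = test, statistic = NA_real_, p_value = NA_real_,
         pass = NA, computed = FALSE, reason = reason)
  }
  as_check <- function(test, statistic, p) {
    list(test = test, statistic = unname(statistic), p_value = unname(p),
         pass = unname(p) > alpha, computed = TRUE, reason = NULL)
  }
  try_check <- function(test, expr) {
    tryCatch(expr, error = function(e) not_computed(test, conditionMessage(e)))
  }

  if (degenerate) {
    checks <- list(
      normality = not_computed("residual normality", "degenerate residuals"),
      homoscedasticity = not_computed("Breusch-Pagan",
                                      "degenerate residuals"),
      independence = not_computed("Durbin-Watson", "degenerate residuals"),
      linearity = not_computed("quadratic augmentation F",
                               "degenerate residuals")
    )
    return(structure(list(checks = checks, alpha = alpha, n = n),
                     class = "regression_diagnostics"))
  }

  normality <- try_check("residual normality", {
    if (n <= 5000) {
      sw <- stats::shapiro.test(res)
      as_check("Shapiro-Wilk", sw$statistic, sw$p.value)
    } else {
      ad <- nortest::ad.test(res)
      as_check("Anderson-Darling", ad$statistic, ad$p.value)
    }
  })
  homoscedasticity <- try_check("Breusch-Pagan", {
    bp <- lmtest::bptest(fit$fit)
    as_check("Breusch-Pagan", bp$statistic, bp$p.value)
  })
  independence <- try_check("Durbin-Watson", {
    dw <- lmtest::dwtest(fit$fit)
    as_check("Durbin-Watson", dw$statistic, dw$p.value)
  })
  linearity <- try_check("quadratic augmentation F", {
    mf <- stats::model.frame(fit$fit)
    num <- names(mf)[-1L]
    num <- num[vapply(mf[num], function(v) {
      is.numeric(v) && length(unique(v)) > 2
    }, logical(1))]
    if (!length(num)) {
      not_computed("quadratic augmentation F", "no continuous predictors")
    } else {
      # Refit on the stored model frame rather than update(): the original
      # data object is a local of the fitting wrapper.
      response <- names(mf)[1L]
      base_terms <- attr(stats::terms(fit$fit), "term.labels")
      sq <- paste0("I(", num, "^2)")
      aug <- stats::lm(stats::reformulate(c(base_terms, sq), response),
                       data = mf)
      an <- stats::anova(fit$fit, aug)
      as_check("quadratic augmentation F", an$F[2L], an$`Pr(>F)`[2L])
    }
  })

  structure(list(checks = list(normality = normality,
                               homoscedasticity = homoscedasticity,
                               independence = independence,
                               linearity = linearity),
                 alpha = alpha, n = n),
            class = "regression_diagnostics")
}

#' @export
print.regression_diagnostics <- function(x, ...) {
  cat(sprintf("Regression diagnostics (n = %d, alpha = %g)\n", x$n, x$alpha))
  for (nm in names(x$checks)) {
    ch <- x$checks[[nm]]
    if (!isTRUE(ch$computed)) {
      cat(sprintf("  %-18s not computed (%s)\n", nm, ch$reason))
    } else {
      cat(sprintf("  %-18s %s: statistic %.3f, p %s -> %s\n", nm, ch$test,
                  ch$statistic, format_p(ch$p_value),
                  if (ch$pass) "pass" else "FAIL"))
    }
  }
  invisible(x)
}
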