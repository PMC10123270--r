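# Synthetic ocular-biometry cohort generator.
#
# The generator draws age, gender and CCT independently, builds the
# stress-strain index (SSI) with prescribed covariances to age and gender,
# then produces the emmetropic axial length and the axial increment from
# linear structural equations in (age, male, SSI). Corneal radius is obtained
# by inverting the emmetropia formula, so the derived al_emmetropia of every
# generated record reproduces its structural value exactly; SER is the
# refraction implied by (AL, CR) plus independent measurement noise.

# Mean and variance of a normal(mean, sd) truncated to [lower, upper].
truncnorm_moments <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z <= 0) stop("empty truncation interval", call. = FALSE)
  pa <- stats::dnorm(a)
  pb <- stats::dnorm(b)
  m <- mean + sd * (pa - pb) / Z
  v <- sd^2 * (1 + (a * pa - b * pb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, var = v)
}

# Inverse-CDF sampler for the truncated normal (deterministic given the
# RNG stream; no rejection step).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- stats::pnorm((lower - mean) / sd)
  hi <- stats::pnorm((upper - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, lo, hi))
}

# Fields a user may set; everything else in a generator_config is derived by
# calibrate_generator() and rejected on input files.
.config_fields <- c(
  "n", "seed", "age_mean", "age_sd", "age_min", "age_max", "p_male",
  "cct_mean", "cct_sd", "ssi_mean", "ssi_sd",
  "emm_coef_age", "emm_coef_male", "emm_coef_ssi",
  "delta_coef_age", "delta_coef_male", "delta_coef_ssi",
  "emm_mean", "emm_sd", "delta_mean", "delta_sd",
  "slope_al", "slope_emm", "slope_delta",
  "ser_noise_sd", "max_retries"
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a young, predominantly myopic refractive-surgery
#' population: moment targets for age, gender, central corneal thickness
#' (CCT) and the stress-strain index (SSI); structural (covariate-adjusted)
#' regression coefficients of emmetropic axial length and of the axial
#' increment on age, male gender and SSI; and the marginal (single-predictor)
#' slopes of the three outcomes on SSI that the generated cohort must
#' reproduce. The CCT coefficient of both structural equations is zero, so
#' CCT acts as a pure noise covariate.
#'
#' The returned object is *uncalibrated*: intercepts, residual SDs and the
#' age/gender-to-SSI confounding coefficients are solved by
#' [calibrate_generator()], which [generate_cohort()] calls automatically.
#'
#' @param n cohort size (one eye per subject).
#' @param seed integer RNG seed; the same seed yields a bit-identical cohort.
#' @param age_mean,age_sd,age_min,age_max years; age is truncated normal.
#' @param p_male proportion of male subjects.
#' @param cct_mean,cct_sd central corneal thickness, micrometers.
#' @param ssi_mean,ssi_sd stress-strain index (unitless).
#' @param emm_coef structural coefficients (age, male, ssi) of the emmetropic
#'   axial length equation, mm per unit.
#' @param delta_coef structural coefficients (age, male, ssi) of the axial
#'   increment equation, mm per unit.
#' @param emm_mean,emm_sd target mean and SD of emmetropic axial length, mm.
#' @param delta_mean,delta_sd target mean and SD of the axial increment, mm.
#' @param slope_al,slope_emm,slope_delta target marginal slopes on SSI of
#'   axial length, emmetropic axial length and axial increment (mm per SSI
#'   unit). `slope_al` is implied by the other two since AL is their sum.
#' @param ser_noise_sd SD of independent refraction measurement noise, D.
#' @param max_retries redraw cap per record for physiological-guard
#'   violations.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- calibrate_generator(generator_config(n = 500, seed = 42))
#' cohort <- generate_cohort(cfg)
#' @export
generator_config <- function(n = 267, seed = 1L,
                             age_mean = 22, age_sd = 8,
                             age_min = 6, age_max = 60,
                             p_male = 0.46,
                             cct_mean = 544, cct_sd = 34,
                             ssi_mean = 0.82, ssi_sd = 0.15,
                             emm_coef = c(age = 0, male = 0.27, ssi = 0.48),
                             delta_coef = c(age = 0.07, male = 0.23,
                                            ssi = -2.49),
                             emm_mean = 23.64, emm_sd = 0.50,
                             delta_mean = 2.38, delta_sd = 1.35,
                             slope_al = -2.04, slope_emm = 0.561,
                             slope_delta = -2.6,
                             ser_noise_sd = 1.4,
                             max_retries = 100L) {
  stopifnot(n >= 0, age_sd > 0, cct_sd > 0, ssi_sd > 0,
            emm_sd > 0, delta_sd > 0, ser_noise_sd >= 0,
            p_male > 0, p_male < 1, age_min < age_max,
            max_retries >= 1)
  stopifnot(all(c("age", "male", "ssi") %in% names(emm_coef)),
            all(c("age", "male", "ssi") %in% names(delta_coef)))
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    p_male = p_male, cct_mean = cct_mean, cct_sd = cct_sd,
    ssi_mean = ssi_mean, ssi_sd = ssi_sd,
    emm_coef = emm_coef[c("age", "male", "ssi")],
    delta_coef = delta_coef[c("age", "male", "ssi")],
    emm_mean = emm_mean, emm_sd = emm_sd,
    delta_mean = delta_mean, delta_sd = delta_sd,
    slope_al = slope_al, slope_emm = slope_emm, slope_delta = slope_delta,
    ser_noise_sd = ser_noise_sd,
    max_retries = as.integer(max_retries),
    calibrated = FALSE
  ), class = "generator_config")
}

#' Calibrate a generator configuration
#'
#' Solves, in closed form, the quantities the moment and slope targets leave
#' implicit:
#' \itemize{
#'   \item the auxiliary coefficients `delta_age = cov(age, SSI)/var(SSI)`
#'     and `delta_male = cov(male, SSI)/var(SSI)` from the 2x2 linear system
#'     equating each marginal slope to its structural coefficient plus
#'     omitted-variable bias,
#'   \item the age and gender loadings of the SSI equation and its residual
#'     SD, so SSI has the target mean and SD with exactly those covariances,
#'   \item intercepts of both structural equations, so the generated means of
#'     emmetropic axial length and axial increment hit their targets,
#'   \item residual SDs of both structural equations, so the generated SDs
#'     hit their targets after subtracting explained variance.
#' }
#' Age moments use the analytic truncated-normal mean and variance, so the
#' calibration is exact in expectation, not approximate.
#'
#' @param config a [generator_config()].
#' @return The config with calibrated fields filled in and
#'   `calibrated = TRUE`.
#' @export
calibrate_generator <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cf <- config
  age <- truncnorm_moments(cf$age_mean, cf$age_sd, cf$age_min, cf$age_max)
  ssi_var <- cf$ssi_sd^2
  male_var <- cf$p_male * (1 - cf$p_male)

  # Omitted-variable bias: marginal slope = structural ssi coefficient
  # + coef_age * delta_age + coef_male * delta_male, for each outcome.
  A <- rbind(c(cf$emm_coef[["age"]], cf$emm_coef[["male"]]),
             c(cf$delta_coef[["age"]], cf$delta_coef[["male"]]))
  rhs <- c(cf$slope_emm - cf$emm_coef[["ssi"]],
           cf$slope_delta - cf$delta_coef[["ssi"]])
  if (abs(det(A)) < 1e-12) {
    stop("calibration infeasible: structural age/male coefficients do not ",
         "identify the confounding structure (singular system)",
         call. = FALSE)
  }
  d <- solve(A, rhs)
  delta_age <- d[1L]
  delta_male <- d[2L]

  # SSI equation loadings from the required covariances.
  a_age <- delta_age * ssi_var / age$var
  d_male <- delta_male * ssi_var / male_var
  explained_ssi <- a_age^2 * age$var + d_male^2 * male_var
  if (explained_ssi >= ssi_var) {
    stop(sprintf(paste0("calibration infeasible: age/gender explain %.4f of ",
                        "SSI variance %.4f (implied correlation >= 1)"),
                 explained_ssi, ssi_var), call. = FALSE)
  }
  ssi_eps_sd <- sqrt(ssi_var - explained_ssi)

  # Covariance matrix of (age, male, ssi) under the generating process.
  cov_age_ssi <- delta_age * ssi_var
  cov_male_ssi <- delta_male * ssi_var
  Sigma <- matrix(c(age$var, 0, cov_age_ssi,
                    0, male_var, cov_male_ssi,
                    cov_age_ssi, cov_male_ssi, ssi_var), 3, 3)

  means <- c(age$mean, cf$p_male, cf$ssi_mean)
  resid_sd <- function(coefs, target_mean, target_sd, label) {
    v <- as.numeric(coefs[c("age", "male", "ssi")])
    expl <- drop(t(v) %*% Sigma %*% v)
    if (expl > target_sd^2) {
      stop(sprintf(paste0("calibration infeasible: structural terms explain ",
                          "variance %.4f of %s but its target SD is %.3f"),
                   expl, label, target_sd), call. = FALSE)
    }
    list(intercept = target_mean - sum(v * means),
         sd = sqrt(target_sd^2 - expl))
  }
  emm <- resid_sd(cf$emm_coef, cf$emm_mean, cf$emm_sd,
                  "emmetropic axial length")
  dl <- resid_sd(cf$delta_coef, cf$delta_mean, cf$delta_sd,
                 "axial increment")

  cf$delta_age <- delta_age
  cf$delta_male <- delta_male
  cf$ssi_age_loading <- a_age
  cf$ssi_male_loading <- d_male
  cf$ssi_eps_sd <- ssi_eps_sd
  cf$age_mean_trunc <- age$mean
  cf$age_var_trunc <- age$var
  cf$emm_intercept <- emm$intercept
  cf$emm_resid_sd <- emm$sd
  cf$delta_intercept <- dl$intercept
  cf$delta_resid_sd <- dl$sd
  cf$calibrated <- TRUE
  cf
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort generator config (n = %d, seed = %d)%s\n",
              x$n, x$seed,
              if (isTRUE(x$calibrated)) ", calibrated" else " [uncalibrated]"))
  cat(sprintf("  age %g (%g) yr in [%g, %g]; male %.0f%%; CCT %g (%g) um\n",
              x$age_mean, x$age_sd, x$age_min, x$age_max,
              100 * x$p_male, x$cct_mean, x$cct_sd))
  cat(sprintf("  SSI %g (%g); targets: ALemm %g (%g) mm, dAL %g (%g) mm\n",
              x$ssi_mean, x$ssi_sd, x$emm_mean, x$emm_sd,
              x$delta_mean, x$delta_sd))
  cat(sprintf("  marginal SSI slopes: AL %g, ALemm %g, dAL %g mm/unit\n",
              x$slope_al, x$slope_emm, x$slope_delta))
  if (isTRUE(x$calibrated)) {
    cat(sprintf("  confounding: delta_age %.4f, delta_male %.4f; ",
                x$delta_age, x$delta_male))
    cat(sprintf("residual SDs: ALemm %.3f, dAL %.3f mm\n",
                x$emm_resid_sd, x$delta_resid_sd))
  }
  invisible(x)
}

#' Generate a synthetic per-eye biometry cohort
#'
#' Deterministic given `config$seed`. One record per subject (right eye).
#' Records violating the physiological guards (corneal radius 5-12 mm, axial
#' length 15-40 mm, SSI 0.2-2.5, CCT 300-800 um) are redrawn in full, up to
#' `max_retries` rounds.
#'
#' @param config a [generator_config()]; calibrated automatically if needed.
#' @param constants Morgan formula constants used to derive corneal radius
#'   and refraction.
#' @return A cohort data.frame with all measured and derived columns.
#' @export
generate_cohort <- function(config = generator_config(),
                            constants = morgan_constants()) {
  stopifnot(inherits(config, "generator_config"))
  if (!isTRUE(config$calibrated)) config <- calibrate_generator(config)
  n <- config$n
  if (n == 0L) return(empty_cohort())

  draw <- function(m) {
    age <- rtruncnorm(m, config$age_mean, config$age_sd,
                      config$age_min, config$age_max)
    male <- stats::rbinom(m, 1L, config$p_male)
    cct <- stats::rnorm(m, config$cct_mean, config$cct_sd)
    ssi <- config$ssi_mean +
      config$ssi_age_loading * (age - config$age_mean_trunc) +
      config$ssi_male_loading * (male - config$p_male) +
      stats::rnorm(m, 0, config$ssi_eps_sd)
    emm <- config$emm_intercept +
      config$emm_coef[["age"]] * age + config$emm_coef[["male"]] * male +
      config$emm_coef[["ssi"]] * ssi +
      stats::rnorm(m, 0, config$emm_resid_sd)
    dal <- config$delta_intercept +
      config$delta_coef[["age"]] * age + config$delta_coef[["male"]] * male +
      config$delta_coef[["ssi"]] * ssi +
      stats::rnorm(m, 0, config$delta_resid_sd)
    al <- emm + dal
    # Corneal radius reproducing the emmetropic length under the model.
    recip <- 1 / emm - constants$c
    cr <- ifelse(recip > 0, constants$a / recip, NA_real_)
    # Inverse Morgan map, NA-propagating (implied_ser() itself rejects NA).
    ser <- (1 / al - constants$a / cr - constants$c) / constants$b +
      stats::rnorm(m, 0, config$ser_noise_sd)
    data.frame(age = age,
               gender = ifelse(male == 1L, "male", "female"),
               ser_d = ser, ssi = ssi, cct_um = cct, cr_mm = cr, al_mm = al,
               stringsAsFactors = FALSE)
  }

  set.seed(config$seed)
  dat <- draw(n)
  ok <- !is.na(dat$cr_mm) & !is.na(dat$ser_d) & guards_ok(dat)
  tries <- 0L
  while (any(!ok) && tries < config$max_retries) {
    idx <- which(!ok)
    redo <- draw(length(idx))
    dat[idx, ] <- redo
    ok[idx] <- !is.na(redo$cr_mm) & !is.na(redo$ser_d) & guards_ok(redo)
    tries <- tries + 1L
  }
  if (any(!ok)) {
    stop("generator failed to produce ", sum(!ok), " record(s) inside the ",
         "physiological guards after ", config$max_retries, " retries",
         call. = FALSE)
  }
  dat <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    eye = "OD", dat, stringsAsFactors = FALSE)
  compute_derived(dat, constants = constants)
}

#' Write a generator configuration to YAML or JSON
#'
#' Only the user-settable fields are stored; calibrated quantities are
#' recomputed on read. Format is chosen by file extension (`.yaml`/`.yml`
#' or `.json`).
#'
#' @param config a [generator_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  flat <- list(
    n = config$n, seed = config$seed,
    age_mean = config$age_mean, age_sd = config$age_sd,
    age_min = config$age_min, age_max = config$age_max,
    p_male = config$p_male,
    cct_mean = config$cct_mean, cct_sd = config$cct_sd,
    ssi_mean = config$ssi_mean, ssi_sd = config$ssi_sd,
    emm_coef_age = config$emm_coef[["age"]],
    emm_coef_male = config$emm_coef[["male"]],
    emm_coef_ssi = config$emm_coef[["ssi"]],
    delta_coef_age = config$delta_coef[["age"]],
    delta_coef_male = config$delta_coef[["male"]],
    delta_coef_ssi = config$delta_coef[["ssi"]],
    emm_mean = config$emm_mean, emm_sd = config$emm_sd,
    delta_mean = config$delta_mean, delta_sd = config$delta_sd,
    slope_al = config$slope_al, slope_emm = config$slope_emm,
    slope_delta = config$slope_delta,
    ser_noise_sd = config$ser_noise_sd,
    max_retries = config$max_retries
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(flat, path)
  } else if (ext == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config extension '.", ext, "' (use .yaml or .json)",
         call. = FALSE)
  }
  invisible(path)
}

#' Read a generator configuration from YAML or JSON
#'
#' Unknown keys are rejected rather than ignored, so typos in a config file
#' cannot silently fall back to defaults.
#'
#' @param path config file path.
#' @return A calibrated [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config extension '.", ext, "' (use .yaml or .json)",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), .config_fields)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  args <- raw
  coef_keys <- function(prefix) {
    ks <- paste0(prefix, "_coef_", c("age", "male", "ssi"))
    if (any(ks %in% names(raw))) {
      defaults <- formals(generator_config)[[paste0(prefix, "_coef")]]
      v <- eval(defaults)
      for (part in c("age", "male", "ssi")) {
        k <- paste0(prefix, "_coef_", part)
        if (k %in% names(raw)) v[[part]] <- raw[[k]]
      }
      v
    } else NULL
  }
  for (prefix in c("emm", "delta")) {
    v <- coef_keys(prefix)
    args[paste0(prefix, "_coef_", c("age", "male", "ssi"))] <- NULL
    if (!is.null(v)) args[[paste0(prefix, "_coef")]] <- v
  }
  calibrate_generator(do.call(generator_config, args))
}
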