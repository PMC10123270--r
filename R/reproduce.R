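# End-to-end pipeline: generate (or accept) a cohort, run every analysis
# stage, and serialize a deterministic report bundle.

# Cheap deterministic fingerprint of the user-settable config fields,
# embedded in every output so bundles can be traced to their configuration.
config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_generator_config(config, tmp)
  b <- utf8ToInt(paste(readLines(tmp, warn = FALSE), collapse = "\n"))
  sprintf("%08x", sum(b * (seq_along(b) %% 9973)) %% 2147483647)
}

fit_to_list <- function(fit) {
  list(label = fit$label, outcome = fit$outcome,
       coefficients = fit$coefficients, n = fit$n,
       r_squared = fit$r_squared, sigma = fit$sigma)
}

diag_to_list <- function(dg) {
  lapply(dg$checks, function(ch) {
    list(test = ch$test, statistic = ch$statistic, p_value = ch$p_value,
         pass = ch$pass, computed = ch$computed, reason = ch$reason)
  })
}

#' Run the full statistical analysis on a cohort
#'
#' Computes, in order: the descriptive summary; Pearson correlation and
#' Bland-Altman agreement between measured axial length and its Morgan
#' estimate; group means of the axial decomposition; the refraction vs
#' axial-increment correlation; the three simple regressions on SSI; the
#' three covariate-adjusted models with diagnostics; and the long-eye
#' (AL >= 26 mm) axial-increment model. Stages that are underpowered on a
#' small cohort (diagnostics, subgroup model) are reported as not computed
#' instead of aborting the bundle.
#'
#' @param table a cohort data.frame; derived columns are computed if absent.
#' @param constants a [morgan_constants()] object.
#' @return A named list of stage results, class `analysis_bundle`.
#' @export
analyze_cohort <- function(table, constants = morgan_constants()) {
  validate_cohort(table)
  if (!all(.derived_cols %in% names(table))) {
    table <- compute_derived(table, constants)
  }
  if (nrow(table) < 3) {
    stop("cohort too small to analyze (n = ", nrow(table), ")",
         call. = FALSE)
  }
  log_stage <- function(stage, n_in, n_out = n_in) {
    message(sprintf("[axelong] %-22s in=%d out=%d", stage, n_in, n_out))
  }
  n <- nrow(table)

  log_stage("descriptive", n)
  descriptive <- descriptive_table(table)

  log_stage("agreement", n)
  agreement <- list(
    pearson = pearson_with_t(table$al_mm, table$al_morgan_mm),
    bland_altman = bland_altman(table$al_mm, table$al_morgan_mm)
  )

  log_stage("group_summary", n)
  groups <- group_summary(table)

  log_stage("ser_delta_correlation", n)
  ser_delta <- pearson_with_t(table$ser_d, table$delta_al_mm)

  log_stage("simple_regressions", n)
  simple <- list(
    al = fit_linear_model(table, "al_mm", "ssi", label = "AL ~ SSI"),
    al_emmetropia = fit_linear_model(table, "al_emmetropia_mm", "ssi",
                                     label = "ALemmetropia ~ SSI"),
    delta_al = fit_linear_model(table, "delta_al_mm", "ssi",
                                label = "deltaAL ~ SSI")
  )

  log_stage("adjusted_models", n)
  adjusted <- tryCatch(run_adjusted_models(table), error = function(e) NULL)
  diagnostics <- if (is.null(adjusted)) NULL else {
    lapply(adjusted, run_diagnostics)
  }

  log_stage("subgroup_model", n, sum(table$al_mm >= 26))
  subgroup <- tryCatch(subgroup_model(table), error = function(e) {
    message("[axelong] subgroup model not computed: ", conditionMessage(e))
    NULL
  })

  structure(list(
    n = n,
    descriptive = descriptive,
    agreement = agreement,
    group_summary = groups,
    ser_delta_correlation = ser_delta,
    simple_regressions = simple,
    adjusted_models = adjusted,
    diagnostics = diagnostics,
    subgroup_model = subgroup
  ), class = "analysis_bundle")
}

bundle_to_list <- function(bundle, meta) {
  cor_to_list <- function(ct) ct[c("r", "t", "df", "p", "n")]
  ba <- bundle$agreement$bland_altman
  list(
    meta = meta,
    n = bundle$n,
    descriptive = bundle$descriptive,
    agreement = list(
      pearson = cor_to_list(bundle$agreement$pearson),
      bland_altman = ba[c("bias", "sd_diff", "loa_low", "loa_high",
                          "multiplier", "n", "direction")]
    ),
    group_summary = bundle$group_summary,
    ser_delta_correlation = cor_to_list(bundle$ser_delta_correlation),
    simple_regressions = lapply(bundle$simple_regressions, fit_to_list),
    adjusted_models = if (is.null(bundle$adjusted_models)) NULL else {
      lapply(bundle$adjusted_models, fit_to_list)
    },
    diagnostics = if (is.null(bundle$diagnostics)) NULL else {
      lapply(bundle$diagnostics, diag_to_list)
    },
    subgroup_model = if (is.null(bundle$subgroup_model)) NULL else {
      fit_to_list(bundle$subgroup_model)
    }
  )
}

# Coefficient table formatted like a clinical regression summary:
# rows intercept/age/male/CCT/SSI, one column block per model.
format_model_table <- function(models) {
  term_order <- c("(Intercept)", "age", "male", "cct_um", "ssi")
  term_label <- c("(Intercept)", "Age", "Male gender", "CCT", "SSI")
  labels <- vapply(models, function(m) m$label, character(1))
  lines <- sprintf("%-14s %-22s %-22s %-22s", "",
                   labels[1], labels[2], labels[3])
  for (i in seq_along(term_order)) {
    cells <- vapply(models, function(m) {
      row <- m$coefficients[m$coefficients$term == term_order[i], ]
      if (!nrow(row)) return("")
      sprintf("%6.2f %-3s [%6.2f,%6.2f]", row$estimate, row$stars,
              row$ci_low, row$ci_high)
    }, character(1))
    lines <- c(lines, sprintf("%-14s %-22s %-22s %-22s", term_label[i],
                              cells[1], cells[2], cells[3]))
  }
  lines <- c(lines, sprintf("%-14s %-22d %-22d %-22d", "N",
                            models[[1]]$n, models[[2]]$n, models[[3]]$n),
             "*** p < 0.001; ** p < 0.01; * p < 0.05")
  lines
}

#' Regenerate the full report bundle from a configuration
#'
#' Generates a synthetic cohort from `config`, runs [analyze_cohort()], and
#' writes a deterministic report bundle to `out_dir`: the cohort CSV, one
#' JSON file per stage, and an aligned-text model table. Every JSON output
#' embeds the seed, a config fingerprint, and the package version, so two
#' runs with the same config and seed are byte-identical. On any stage
#' error the partial outputs are removed and the error names the stage.
#'
#' @param config a [generator_config()], or the path of a YAML/JSON config
#'   file.
#' @param out_dir output directory (created if needed).
#' @param seed optional override of the config seed.
#' @return The `analysis_bundle`, invisibly.
#' @export
reproduce <- function(config = generator_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_generator_config(config)
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  written <- character(0)
  stage <- "setup"
  on_error <- function(e) {
    unlink(written)
    stop("reproduce failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "generate"
    cohort <- generate_cohort(config)
    stage <- "analyze"
    bundle <- analyze_cohort(cohort)
    stage <- "write"
    meta <- list(seed = config$seed, n = config$n,
                 config_fingerprint = config_fingerprint(config),
                 package = "axelong",
                 version = as.character(utils::packageVersion("axelong")))
    path <- function(f) {
      p <- file.path(out_dir, f)
      written <<- c(written, p)
      p
    }
    write_cohort(cohort, path("cohort.csv"))
    out <- bundle_to_list(bundle, meta)
    for (nm in setdiff(names(out), c("meta", "n"))) {
      jsonlite::write_json(list(meta = meta, result = out[[nm]]),
                           path(paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           dataframe = "rows")
    }
    if (!is.null(bundle$adjusted_models)) {
      writeLines(format_model_table(bundle$adjusted_models),
                 path("adjusted_models.txt"))
    }
    invisible(bundle)
  }, error = on_error)
}
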