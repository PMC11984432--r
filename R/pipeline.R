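# One-config orchestration: simulate -> filter -> clock (LOOCV) ->
# delta age -> behavior models, with diff-able TSV outputs. Every
# stochastic stage derives its seed from the global seed plus a fixed
# stage offset, so stages are reproducible independently of each other.

STAGE_SEED_OFFSETS <- c(cohort = 1L, aging = 2L, methylation = 3L,
                        behavior = 4L, clock = 10L)

#' Default pipeline configuration
#'
#' Returns the full configuration list that \code{\link{run_pipeline}}
#' uses when a field is not supplied, suitable as a template to edit
#' and write back out as YAML.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(seed = 1L,
       stages = list(methylation = TRUE, behavior = TRUE),
       cohort = list(), aging = list(), methylation = list(),
       behavior = list(),
       clock = list(alpha = 0.5, nfolds = 10),
       delta = list(threshold = 1.0))
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; unknown fields are rejected
#' and every violation is reported with the field name and the violated
#' constraint. A missing seed defaults to 1 with a warning.
#'
#' @param config Path to a YAML file, or a list.
#' @return A validated configuration list of class \code{"run_config"}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_param("config must be a list or a YAML path")
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown top-level field '%s'", unknown))
  }
  for (nm in intersect(names(config), names(base))) {
    if (nm %in% c("seed")) next
    base[[nm]] <- utils::modifyList(base[[nm]], as.list(config[[nm]]))
  }
  if (is.null(config$seed)) {
    warning("config has no seed; defaulting to 1")
  } else {
    base$seed <- config$seed
  }
  if (!is.numeric(base$seed) || length(base$seed) != 1 ||
      base$seed != floor(base$seed)) {
    errors <- c(errors, "seed: must be a single integer")
  }
  al <- base$clock$alpha
  if (!is.numeric(al) || length(al) != 1 || al < 0 || al > 1) {
    errors <- c(errors, "clock.alpha: must lie in [0, 1]")
  }
  if (!is.numeric(base$delta$threshold) || base$delta$threshold <= 0) {
    errors <- c(errors, "delta.threshold: must be > 0")
  }
  # spec constructors enforce their own invariants; surface their messages
  for (check in list(
    c("cohort", "cohort_spec"), c("aging", "aging_rate_spec"),
    c("methylation", "methylation_sim_spec"),
    c("behavior", "behavior_sim_spec"))) {
    msg <- tryCatch({
      do.call(check[2], base[[check[1]]])
      NULL
    }, error = function(e) sprintf("%s: %s", check[1], conditionMessage(e)))
    if (!is.null(msg)) errors <- c(errors, msg)
  }
  if (length(errors)) {
    stop_param("invalid configuration:\n  %s",
               paste(errors, collapse = "\n  "))
  }
  base$seed <- as.integer(base$seed)
  class(base) <- "run_config"
  base
}

write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(format(x, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — cohort simulation, biological
#' ages, methylation simulation, site-exclusion cascade, leave-one-out
#' clock predictions, delta-age records and summaries, behavior simulation
#' and association models — and writes each product as a TSV under
#' \code{out_dir} along with a plain-text summary report.
#'
#' @param config A \code{\link{validate_config}} result, a list, or a YAML
#'   path.
#' @param out_dir Output directory.
#' @return An object of class \code{"run_report"} (invisibly) collecting
#'   the filter report, clock fit summary, category summaries, fitted
#'   models and provenance.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  provenance <- sprintf("epiage run, seed=%d, config_hash=%s",
                        seed, config_hash(config))

  stage_args <- function(part, offset) {
    utils::modifyList(as.list(config[[part]]),
                      list(seed = seed + STAGE_SEED_OFFSETS[[offset]]))
  }
  cohort <- simulate_cohort(do.call(cohort_spec,
                                    stage_args("cohort", "cohort")))
  bio <- simulate_biological_ages(cohort, do.call(aging_rate_spec,
                                                  stage_args("aging", "aging")))
  write_tsv(cohort, file.path(out_dir, "cohort.tsv"), provenance)

  report <- list(provenance = provenance, seed = seed)

  if (isTRUE(config$stages$methylation)) {
    sim <- simulate_methylation(cohort, bio,
      do.call(methylation_sim_spec, stage_args("methylation", "methylation")))
    casc <- run_filter_cascade(sim$matrix, sim$snp_bed)
    write_tsv(as.data.frame(casc$report),
              file.path(out_dir, "filter_report.tsv"), provenance)

    cv <- loocv_clock(casc$matrix, cohort$age,
                      alpha = config$clock$alpha,
                      nfolds = config$clock$nfolds,
                      seed = seed + STAGE_SEED_OFFSETS[["clock"]])
    write_tsv(as.data.frame(cv), file.path(out_dir, "predictions.tsv"),
              provenance)
    records <- delta_age_records(cv, threshold = config$delta$threshold)
    write_tsv(records, file.path(out_dir, "delta_age.tsv"), provenance)
    summaries <- rbind(summarize_categories(records, "diff"),
                       summarize_categories(records, "resid"))
    write_tsv(summaries, file.path(out_dir, "category_summary.tsv"),
              provenance)
    cvs <- summary(cv)
    report$filter_report <- casc$report
    report$clock_summary <- list(
      r = cvs$r, mae = cvs$mae,
      median_lambda = stats::median(attr(cv, "fold_lambda")),
      median_nonzero = cvs$median_nonzero)
    report$category_summary <- summaries
    report$records <- records
    report$predictions <- cv
  }

  if (isTRUE(config$stages$behavior)) {
    beh <- simulate_behavior(cohort, do.call(behavior_sim_spec,
      stage_args("behavior", "behavior")))
    sp <- walking_speed(beh$bouts)
    mo <- motor_performance(beh$trials)
    ind <- cohort
    ind$speed <- sp$speed[match(ind$subject_id, sp$subject_id)]
    ind$motor_rate <- mo$rate[match(ind$subject_id, mo$subject_id)]
    if (!is.null(report$records)) {
      ind$epigenetic_age <- report$records$epigenetic_age[
        match(ind$subject_id, report$records$subject_id)]
    }
    write_tsv(ind, file.path(out_dir, "behavior_indicators.tsv"),
              provenance)

    regs <- list(speed_chronological =
                   fit_age_regression(ind, "speed", "age"),
                 motor_chronological =
                   fit_age_regression(ind, "motor_rate", "age"))
    if (!is.null(ind$epigenetic_age)) {
      regs$speed_epigenetic <-
        fit_age_regression(ind, "speed", "epigenetic_age")
      regs$motor_epigenetic <-
        fit_age_regression(ind, "motor_rate", "epigenetic_age")
    }
    reg_tab <- do.call(rbind, lapply(names(regs), function(nm) {
      r <- regs[[nm]]
      data.frame(model = nm, n = r$n, F = r$F, df1 = r$df1, df2 = r$df2,
                 p = r$model_p, adj_r_squared = r$adj_r_squared,
                 age_beta = r$coefficients$estimate[
                   r$coefficients$term == r$age_var],
                 stringsAsFactors = FALSE)
    }))
    write_tsv(reg_tab, file.path(out_dir, "regressions.tsv"), provenance)
    report$regressions <- regs

    if (!is.null(report$records)) {
      anovas <- list()
      for (m in c("diff", "resid")) {
        dat <- ind
        dat$category <- report$records[[paste0("category_", m)]][
          match(dat$subject_id, report$records$subject_id)]
        anovas[[paste0("speed_", m)]] <-
          try(anova_category(dat, "speed"), silent = TRUE)
        anovas[[paste0("delta_", m)]] <-
          try(anova_delta_by_demographics(report$records, cohort, m),
              silent = TRUE)
      }
      report$anovas <- anovas[!vapply(anovas, inherits, TRUE, "try-error")]
    }
  }

  class(report) <- "run_report"
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(report)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_report <- function(x, ...) {
  cat(x$provenance, "\n")
  if (!is.null(x$filter_report)) print(x$filter_report)
  if (!is.null(x$clock_summary)) {
    cat(sprintf("Clock LOOCV: r = %.3f, MAE = %.2f y, median lambda = %.4g, median nonzero = %.0f\n",
                x$clock_summary$r, x$clock_summary$mae,
                x$clock_summary$median_lambda,
                x$clock_summary$median_nonzero))
  }
  if (!is.null(x$category_summary)) {
    cat("Delta-age categories:\n")
    print(x$category_summary, digits = 3)
  }
  if (!is.null(x$regressions)) {
    for (nm in names(x$regressions)) {
      r <- x$regressions[[nm]]
      cat(sprintf("%s: F(%d, %d) = %.2f, adj R2 = %.3f, age beta = %.4f\n",
                  nm, r$df1, r$df2, r$F, r$adj_r_squared,
                  r$coefficients$estimate[r$coefficients$term == r$age_var]))
    }
  }
  invisible(x)
}
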