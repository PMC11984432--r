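# Behavioral aging indicators and their association models: per-subject
# walking speed (m/s, mean of per-bout distance/time ratios) and fine
# motor performance (raisins retrieved per second on a Brinkman-style
# board), modelled on (epigenetic) age with sex and rearing covariates,
# and compared across age-acceleration categories by main-effects ANOVA
# with Bonferroni post-hoc tests.

#' Per-subject walking speed
#'
#' Speed per bout is distance / time; the subject's indicator is the
#' unweighted mean of its bout speeds (mean of ratios, not ratio of sums).
#' Subjects with fewer than \code{min_bouts} recorded bouts are flagged
#' and should be excluded from models.
#'
#' @param bouts data.frame with \code{subject_id}, \code{distance} (m),
#'   \code{time} (s).
#' @param min_bouts Minimum number of bouts for inclusion (default 10).
#' @return data.frame with \code{subject_id}, \code{n_bouts}, \code{speed}
#'   (m/s) and logical \code{included}.
#' @export
walking_speed <- function(bouts, min_bouts = 10) {
  stopifnot(all(c("subject_id", "distance", "time") %in% names(bouts)))
  bad <- which(!(bouts$distance > 0) | !(bouts$time > 0))
  if (length(bad)) {
    stop_param("bout %d has non-positive distance or time (subject %s)",
               bad[1], bouts$subject_id[bad[1]])
  }
  speed <- bouts$distance / bouts$time
  agg <- tapply(speed, bouts$subject_id, mean)
  nb <- tapply(speed, bouts$subject_id, length)
  data.frame(subject_id = names(agg),
             n_bouts = as.integer(nb),
             speed = as.numeric(agg),
             included = as.integer(nb) >= min_bouts,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-subject fine motor performance
#'
#' The per-trial rate is raisins retrieved / elapsed seconds; the subject's
#' indicator is the mean rate over its trials. Failed trials (those that
#' hit the 3-minute cap) contribute their retrieved count over 180 s by
#' default; set \code{include_failed = FALSE} to drop them instead.
#' Subjects left with no usable trials are omitted.
#'
#' @param trials data.frame with \code{subject_id}, \code{raisins},
#'   \code{elapsed} (s) and logical \code{failed}.
#' @param include_failed Keep failed trials at the 180 s cap (default TRUE).
#' @return data.frame with \code{subject_id}, \code{n_trials} and
#'   \code{rate} (raisins/s).
#' @export
motor_performance <- function(trials, include_failed = TRUE) {
  stopifnot(all(c("subject_id", "raisins", "elapsed") %in% names(trials)))
  if (is.null(trials$failed)) trials$failed <- FALSE
  if (!include_failed) trials <- trials[!trials$failed, , drop = FALSE]
  if (nrow(trials) == 0) {
    return(data.frame(subject_id = character(0), n_trials = integer(0),
                      rate = numeric(0), stringsAsFactors = FALSE))
  }
  if (any(trials$elapsed <= 0)) stop_param("non-positive elapsed time")
  rate <- trials$raisins / trials$elapsed
  agg <- tapply(rate, trials$subject_id, mean)
  nt <- tapply(rate, trials$subject_id, length)
  data.frame(subject_id = names(agg),
             n_trials = as.integer(nt),
             rate = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Drop unknown-rearing subjects and relevel covariates with female/mother
# as reference (treatment coding).
prepare_model_frame <- function(data, outcome) {
  if (!outcome %in% names(data)) {
    stop_param("outcome column '%s' not found", outcome)
  }
  df <- data[!is.na(data[[outcome]]), , drop = FALSE]
  if (!is.null(df$rearing)) {
    df <- df[df$rearing != "unknown", , drop = FALSE]
    df$rearing <- factor(as.character(df$rearing),
                         levels = c("mother", "nursery"))
  }
  if (!is.null(df$sex)) {
    df$sex <- factor(as.character(df$sex), levels = c("female", "male"))
  }
  df
}

#' Hierarchical age regression for a behavioral indicator
#'
#' Ordinary least squares of the outcome on sex (female reference) and
#' rearing (mother reference) plus one age variable (chronological or
#' epigenetic), mirroring a two-block hierarchical regression whose final
#' block is reported. Subjects of unknown rearing are excluded.
#'
#' @param data data.frame with the outcome column, \code{sex},
#'   \code{rearing}, and the age column named by \code{age_var}.
#' @param outcome Name of the outcome column (e.g. \code{"speed"}).
#' @param age_var Name of the age column (default \code{"age"}; use e.g.
#'   \code{"epigenetic_age"} for the epigenetic-age model).
#' @return An object of class \code{"age_regression"} with the coefficient
#'   table, overall F and df, p, R-squared, adjusted R-squared and n.
#' @export
fit_age_regression <- function(data, outcome, age_var = "age") {
  df <- prepare_model_frame(data, outcome)
  if (!age_var %in% names(df)) {
    stop_param("age column '%s' not found", age_var)
  }
  form <- stats::as.formula(
    paste(outcome, "~ sex + rearing +", age_var))
  mm <- stats::model.matrix(form, df)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    bad <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop_param("collinear design: column '%s' is redundant", bad[1])
  }
  if (nrow(df) <= ncol(mm)) stop_param("too few subjects for the model")
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t", "p")
  coefs$term <- rownames(coefs)
  rownames(coefs) <- NULL
  fstat <- sm$fstatistic
  structure(list(
    outcome = outcome, age_var = age_var,
    coefficients = coefs[, c("term", "estimate", "se", "t", "p")],
    F = unname(fstat[1]), df1 = unname(fstat[2]), df2 = unname(fstat[3]),
    model_p = stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    n = nrow(df),
    model = fit), class = "age_regression")
}

#' @export
print.age_regression <- function(x, ...) {
  cat(sprintf("Regression of %s on sex + rearing + %s (n = %d)\n",
              x$outcome, x$age_var, x$n))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.4g, R2 = %.3f, adj R2 = %.3f\n",
              x$df1, x$df2, x$F, x$model_p, x$r_squared, x$adj_r_squared))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.age_regression <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

# Main-effects ANOVA engine: per-factor partial F tests (equivalently
# Type-II/III, identical in the absence of interactions), raw group
# means/SEM for the focal factor, Bonferroni pairwise post-hoc using the
# pooled residual mean square.
main_effects_anova <- function(df, outcome, factors, focal) {
  keep <- character(0)
  for (f in factors) {
    df[[f]] <- droplevels(factor(df[[f]]))
    if (nlevels(df[[f]]) >= 2) keep <- c(keep, f) else {
      warning(sprintf("factor '%s' has a single observed level; dropped", f))
    }
  }
  if (!length(keep)) stop_param("no estimable factors")
  if (!focal %in% keep) {
    stop_param("focal factor '%s' is not estimable", focal)
  }
  form <- stats::as.formula(paste(outcome, "~", paste(keep, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  dr <- stats::drop1(fit, test = "F")
  facts <- data.frame(term = rownames(dr)[-1],
                      df = dr$Df[-1],
                      F = dr$`F value`[-1],
                      p = dr$`Pr(>F)`[-1],
                      stringsAsFactors = FALSE)
  facts$df_resid <- fit$df.residual

  y <- df[[outcome]]
  g <- df[[focal]]
  stats_tab <- do.call(rbind, lapply(levels(g), function(lv) {
    yy <- y[g == lv]
    data.frame(level = lv, n = length(yy), mean = mean(yy),
               sem = stats::sd(yy) / sqrt(length(yy)),
               stringsAsFactors = FALSE)
  }))

  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  npairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(npairs), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    na <- sum(g == a); nb <- sum(g == b)
    diff <- mean(y[g == a]) - mean(y[g == b])
    se <- sqrt(mse * (1 / na + 1 / nb))
    tval <- diff / se
    p_raw <- 2 * stats::pt(abs(tval), fit$df.residual, lower.tail = FALSE)
    data.frame(level_a = a, level_b = b, diff = diff, t = tval,
               p_raw = p_raw, p_bonferroni = min(1, p_raw * npairs),
               stringsAsFactors = FALSE)
  }))

  structure(list(outcome = outcome, focal = focal,
                 factors = facts, group_stats = stats_tab,
                 posthoc = posthoc, n = nrow(df), model = fit),
            class = "behavior_anova")
}

#' @export
print.behavior_anova <- function(x, ...) {
  cat(sprintf("Main-effects ANOVA: %s ~ %s (n = %d)\n", x$outcome,
              paste(x$factors$term, collapse = " + "), x$n))
  for (i in seq_len(nrow(x$factors))) {
    cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.4g\n",
                x$factors$term[i], x$factors$df[i], x$factors$df_resid[i],
                x$factors$F[i], x$factors$p[i]))
  }
  cat(sprintf("Group means (%s):\n", x$focal))
  print(x$group_stats, digits = 3)
  cat("Bonferroni post-hoc:\n")
  print(x$posthoc[, c("level_a", "level_b", "diff", "p_bonferroni")],
        digits = 3)
  invisible(x)
}

#' ANOVA of a behavioral indicator across acceleration categories
#'
#' Univariate main-effects ANOVA of the outcome on the age-acceleration
#' category (-1/0/+1), sex, and rearing (unknown rearing excluded), with
#' raw group means/SEM per category and Bonferroni-adjusted pairwise
#' post-hoc tests on the category factor. Interactions are not modelled.
#'
#' @param data data.frame with the outcome column, \code{category} (values
#'   in \{-1, 0, +1\}), \code{sex} and \code{rearing}.
#' @param outcome Name of the outcome column.
#' @return An object of class \code{"behavior_anova"}.
#' @export
anova_category <- function(data, outcome) {
  df <- prepare_model_frame(data, outcome)
  if (is.null(df$category)) stop_param("'category' column required")
  main_effects_anova(df, outcome, c("category", "sex", "rearing"),
                     focal = "category")
}

#' ANOVA of delta age across demographics
#'
#' Main-effects ANOVA of a delta-age measure on sex, rearing and age group
#' (four levels), with Bonferroni post-hoc over the six age-group pairs.
#' \code{adults_only = TRUE} restricts to young and older adults and tests
#' the two-level age-group factor, the design used to unconfound rearing
#' from the juvenile group.
#'
#' @param records Output of \code{\link{delta_age_records}}.
#' @param cohort Cohort table with \code{subject_id}, \code{sex},
#'   \code{rearing}.
#' @param measure \code{"diff"} or \code{"resid"}.
#' @param adults_only Restrict to young_adult and older_adult subjects.
#' @return An object of class \code{"behavior_anova"}.
#' @export
anova_delta_by_demographics <- function(records, cohort,
                                        measure = c("diff", "resid"),
                                        adults_only = FALSE) {
  measure <- match.arg(measure)
  df <- merge(records, cohort[, c("subject_id", "sex", "rearing")],
              by = "subject_id")
  outcome <- paste0("delta_", measure)
  if (adults_only) {
    df <- df[df$age_group %in% c("young_adult", "older_adult"), ,
             drop = FALSE]
  }
  df <- prepare_model_frame(df, outcome)
  main_effects_anova(df, outcome, c("sex", "rearing", "age_group"),
                     focal = "age_group")
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return A list with \code{r}, \code{df} and \code{p}.
#' @export
correlate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop_param("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    stop_param("zero variance input; correlation undefined")
  }
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Convert a speed from m/s to inches per minute
#'
#' @param speed Speed in meters per second.
#' @return Speed in inches per minute (exact; rounding left to the caller).
#' @export
speed_to_inches_per_minute <- function(speed) {
  stopifnot(all(is.finite(speed)))
  speed * 39.3701 * 60
}
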