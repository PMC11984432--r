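# Delta age: the signed discrepancy between epigenetic and chronological
# age, in two flavours. The raw difference (epigenetic - chronological)
# reads directly as years of acceleration; the residual measure removes
# the cohort-level linear trend of epigenetic on chronological age, so it
# is centered at zero by construction.

#' Raw delta age
#'
#' @param epigenetic,chronological Ages in years.
#' @return epigenetic - chronological; positive values indicate age
#'   acceleration.
#' @export
delta_diff <- function(epigenetic, chronological) {
  stopifnot(all(is.finite(epigenetic)), all(is.finite(chronological)))
  epigenetic - chronological
}

#' Residual delta age
#'
#' Regresses epigenetic age onto chronological age across the whole cohort
#' (ordinary least squares, single cohort-level fit) and returns the
#' unstandardized residuals.
#'
#' @param predictions data.frame with \code{chronological_age} and
#'   \code{epigenetic_age} (e.g. an \code{\link{loocv_clock}} result).
#' @return Numeric vector of residuals (years), summing to zero.
#' @export
delta_resid <- function(predictions) {
  stopifnot(nrow(predictions) >= 3)
  if (stats::sd(predictions$chronological_age) == 0) {
    stop_param("chronological ages are constant; residual delta undefined")
  }
  fit <- stats::lm(epigenetic_age ~ chronological_age, data = predictions)
  as.numeric(stats::residuals(fit))
}

#' Categorize a delta age
#'
#' Subjects within the threshold of a perfect match are scored 0; a delta
#' at or beyond +threshold scores +1 (age acceleration), at or beyond
#' -threshold scores -1 (age deceleration). The +/-1.00-year endpoints
#' belong to the accelerated/decelerated categories.
#'
#' @param delta Delta ages in years.
#' @param threshold Positive category threshold in years (default 1).
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
categorize_delta <- function(delta, threshold = 1.0) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_param("'threshold' must be a single positive number")
  }
  stopifnot(all(is.finite(delta)))
  ifelse(delta <= -threshold, -1L, ifelse(delta >= threshold, 1L, 0L))
}

#' Assign an age group
#'
#' Half-open bins: juvenile [0, 5), young adult [5, 10), older adult
#' [10, 15), geriatric [15, Inf).
#'
#' @param age Chronological ages in years (>= 0).
#' @return Factor with levels juvenile, young_adult, older_adult,
#'   geriatric.
#' @export
assign_age_group <- function(age) {
  if (any(age < 0)) stop_param("ages must be non-negative")
  cut(age, breaks = c(0, 5, 10, 15, Inf), right = FALSE,
      labels = c("juvenile", "young_adult", "older_adult", "geriatric"),
      include.lowest = TRUE)
}

#' Per-subject delta-age records
#'
#' Combines cross-validated age predictions into the full per-subject
#' record: both delta measures, both category assignments, and age group.
#'
#' @param predictions data.frame with \code{subject_id},
#'   \code{chronological_age}, \code{epigenetic_age}.
#' @param threshold Category threshold in years.
#' @return data.frame with columns \code{subject_id},
#'   \code{chronological_age}, \code{epigenetic_age}, \code{delta_diff},
#'   \code{delta_resid}, \code{category_diff}, \code{category_resid},
#'   \code{age_group}.
#' @export
delta_age_records <- function(predictions, threshold = 1.0) {
  dd <- delta_diff(predictions$epigenetic_age,
                   predictions$chronological_age)
  dr <- delta_resid(predictions)
  data.frame(subject_id = predictions$subject_id,
             chronological_age = predictions$chronological_age,
             epigenetic_age = predictions$epigenetic_age,
             delta_diff = dd,
             delta_resid = dr,
             category_diff = categorize_delta(dd, threshold),
             category_resid = categorize_delta(dr, threshold),
             age_group = assign_age_group(predictions$chronological_age),
             stringsAsFactors = FALSE)
}

#' Summarize acceleration/deceleration categories
#'
#' Counts, mean/min/max delta and integer-rounded percentages per category
#' (-1 deceleration, 0 match, +1 acceleration) for one delta measure.
#'
#' @param records Output of \code{\link{delta_age_records}}, or any
#'   data.frame with \code{delta_<measure>} and \code{category_<measure>}.
#' @param measure \code{"diff"} or \code{"resid"}.
#' @return data.frame with one row per category: \code{category}, \code{n},
#'   \code{percent}, \code{mean_delta}, \code{min_delta}, \code{max_delta}.
#' @export
summarize_categories <- function(records, measure = c("diff", "resid")) {
  measure <- match.arg(measure)
  stopifnot(nrow(records) > 0)
  delta <- records[[paste0("delta_", measure)]]
  cat_ <- records[[paste0("category_", measure)]]
  out <- do.call(rbind, lapply(c(-1L, 0L, 1L), function(k) {
    sel <- cat_ == k
    data.frame(category = k,
               n = sum(sel),
               percent = round(100 * sum(sel) / length(cat_)),
               mean_delta = if (any(sel)) mean(delta[sel]) else NA_real_,
               min_delta = if (any(sel)) min(delta[sel]) else NA_real_,
               max_delta = if (any(sel)) max(delta[sel]) else NA_real_)
  }))
  out$measure <- measure
  out
}

#' Compare the two delta-age measures
#'
#' @param records Output of \code{\link{delta_age_records}}.
#' @return A list with \code{r} (Pearson correlation between the two delta
#'   measures), \code{p} (two-sided), and \code{table}, the 3x3 category
#'   cross-tabulation (diff rows, resid columns).
#' @export
compare_measures <- function(records) {
  stopifnot(nrow(records) >= 3)
  if (stats::sd(records$delta_diff) == 0 ||
      stats::sd(records$delta_resid) == 0) {
    stop_param("a delta measure has zero variance; correlation undefined")
  }
  ct <- stats::cor.test(records$delta_diff, records$delta_resid)
  tab <- table(factor(records$category_diff, levels = c(-1, 0, 1)),
               factor(records$category_resid, levels = c(-1, 0, 1)),
               dnn = c("diff", "resid"))
  list(r = unname(ct$estimate), p = ct$p.value, table = tab)
}
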