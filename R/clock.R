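# Elastic-net epigenetic clock.
#
# The clock is a sparse penalized linear model mapping per-CpG methylation
# fractions to chronological age: predictors are per-site z-scored
# methylation levels, the response is age in years, the penalty is an even
# L1/L2 mix (alpha = 0.5) with lambda chosen to minimize cross-validated
# MSE. Held-out age estimates come from leave-one-out refits of the whole
# pipeline (normalization constants, lambda selection, coefficients).

# Accept a meth_matrix or a sites x samples numeric matrix with site-id
# rownames; return samples x sites for the regression code.
as_predictor_matrix <- function(x) {
  if (inherits(x, "meth_matrix")) {
    if (anyNA(x$fraction)) {
      stop_param("matrix has missing cells; run the filter cascade first")
    }
    t(x$fraction)
  } else {
    x <- as.matrix(x)
    if (is.null(rownames(x))) {
      stop_param("a plain matrix needs site identifiers as rownames")
    }
    if (anyNA(x)) stop_param("matrix has missing cells")
    t(x)
  }
}

#' Per-site z-score normalization
#'
#' Centers and scales each CpG site. When \code{constants} is NULL the
#' constants are estimated (mean and sample standard deviation per site;
#' zero-variance sites get scale 1) and returned for reuse; otherwise the
#' supplied training-set constants are reapplied, as required for held-out
#' samples.
#'
#' @param x A \code{\link{meth_matrix}} or sites x samples matrix.
#' @param constants Optional list with named vectors \code{center} and
#'   \code{scale} from a previous call.
#' @return A list with \code{values} (normalized sites x samples matrix),
#'   \code{center} and \code{scale}.
#' @export
normalize_sites <- function(x, constants = NULL) {
  xp <- as_predictor_matrix(x) # samples x sites
  if (is.null(constants)) {
    center <- colMeans(xp)
    scale <- apply(xp, 2, stats::sd)
    scale[scale == 0 | is.na(scale)] <- 1
  } else {
    missing <- setdiff(colnames(xp), names(constants$center))
    absent <- setdiff(names(constants$center), colnames(xp))
    if (length(absent)) {
      stop_param("matrix is missing %d site(s) required by the constants (e.g. %s)",
                 length(absent), absent[1])
    }
    xp <- xp[, names(constants$center), drop = FALSE]
    center <- constants$center
    scale <- constants$scale
  }
  values <- t((xp - rep(center, each = nrow(xp))) /
                rep(scale, each = nrow(xp)))
  list(values = values, center = center, scale = scale)
}

make_foldid <- function(n, nfolds, seed) {
  with_seed(seed, sample(rep(seq_len(nfolds), length.out = n)))
}

#' Fit an elastic-net epigenetic clock
#'
#' Fits \code{glmnet} on z-scored methylation fractions with mixing
#' parameter \code{alpha} (default 0.5). Unless \code{lambda} is supplied,
#' the penalty is chosen by internal k-fold cross-validation as the value
#' minimizing mean squared error over a descending path of
#' \code{nlambda} values spanning four decades below the smallest
#' all-zero penalty; ties go to the largest (sparsest) lambda.
#'
#' @param x A complete (post-cascade) \code{\link{meth_matrix}} or a
#'   sites x samples matrix with site-id rownames.
#' @param age Chronological ages in years, one per sample.
#' @param alpha Elastic-net mixing parameter in [0, 1].
#' @param nfolds Internal CV folds (reduced with a warning when there are
#'   fewer samples than folds).
#' @param lambda Optional fixed penalty, bypassing the internal CV.
#' @param seed Seed for the CV fold shuffle.
#' @param nlambda,lambda.min.ratio Penalty path resolution and depth.
#' @return An object of class \code{"epiclock"}: intercept (years), sparse
#'   site weights, per-site normalization constants, hyperparameters and
#'   the in-sample fit.
#' @export
epiclock <- function(x, age, alpha = 0.5, nfolds = 10, lambda = NULL,
                     seed = NULL, nlambda = 100, lambda.min.ratio = 1e-4) {
  if (alpha < 0 || alpha > 1) stop_param("'alpha' must lie in [0, 1]")
  if (!is.null(lambda) && lambda < 0) stop_param("'lambda' must be >= 0")
  nfolds <- check_count(nfolds, "nfolds", min = 2)
  norm <- normalize_sites(x)
  X <- t(norm$values) # samples x sites
  n <- nrow(X)
  if (length(age) != n) stop_param("length(age) != number of samples")
  if (!all(is.finite(age))) stop_param("ages must be finite")

  if (stats::sd(age) == 0) {
    warning("constant ages: returning an intercept-only clock")
    return(new_epiclock(mean(age), numeric(0), norm, alpha, NA_real_,
                        nfolds, seed, X, age))
  }

  # glmnet requires >= 2 predictor columns; pad with an all-zero dummy
  # (zero variance, so its coefficient is identically zero)
  padded <- ncol(X) < 2
  if (padded) X <- cbind(X, `..pad` = 0)

  cv_curve <- NULL
  if (is.null(lambda)) {
    nfolds_eff <- nfolds
    if (n < nfolds) {
      nfolds_eff <- n
      warning(sprintf("only %d samples: internal CV reduced to %d folds",
                      n, nfolds_eff))
    }
    if (nfolds_eff < 3) stop_param("need at least 3 samples for internal CV")
    foldid <- make_foldid(n, nfolds_eff, seed)
    cv <- glmnet::cv.glmnet(X, age, alpha = alpha, foldid = foldid,
                            standardize = FALSE, nlambda = nlambda,
                            lambda.min.ratio = lambda.min.ratio)
    lambda <- cv$lambda.min
    cv_curve <- data.frame(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                           nzero = as.integer(cv$nzero))
    co <- stats::coef(cv, s = "lambda.min")
  } else {
    # fit along a descending path that ends exactly at the requested
    # lambda: warm starts stabilize convergence and coef() needs no
    # interpolation or refit
    lam_path <- sort(unique(c(lambda, lambda + 10^seq(2, -4, length.out = 20))),
                     decreasing = TRUE)
    fit <- glmnet::glmnet(X, age, alpha = alpha, standardize = FALSE,
                          lambda = lam_path, thresh = 1e-12)
    co <- stats::coef(fit, s = lambda)
  }
  co <- as.matrix(co)[, 1]
  intercept <- co[["(Intercept)"]]
  w <- co[-1]
  if (padded) w <- w[names(w) != "..pad"]
  w <- w[w != 0]
  obj <- new_epiclock(intercept, w, norm, alpha, lambda, nfolds, seed,
                      X, age)
  obj$cv <- cv_curve
  obj
}

new_epiclock <- function(intercept, weights, norm, alpha, lambda, nfolds,
                         seed, X, age) {
  keep <- names(weights)
  fitted <- as.numeric(intercept +
    (if (length(keep)) X[, keep, drop = FALSE] %*% weights else 0))
  structure(list(intercept = intercept,
                 weights = weights,
                 center = norm$center[keep],
                 scale = norm$scale[keep],
                 alpha = alpha, lambda = lambda,
                 nfolds = nfolds, seed = seed,
                 n_nonzero = length(weights),
                 n_train = length(age),
                 n_candidate_sites = length(norm$center),
                 training = data.frame(chronological_age = age,
                                       fitted_age = fitted)),
            class = "epiclock")
}

#' @export
print.epiclock <- function(x, ...) {
  cat("Elastic-net epigenetic clock\n")
  cat(sprintf("  candidate sites: %d, weighted sites: %d\n",
              x$n_candidate_sites, x$n_nonzero))
  cat(sprintf("  alpha = %.2f, lambda = %s\n", x$alpha,
              format(x$lambda, digits = 4)))
  cat(sprintf("  intercept = %.3f years, trained on %d samples\n",
              x$intercept, x$n_train))
  invisible(x)
}

#' @export
summary.epiclock <- function(object, ...) {
  tr <- object$training
  r <- if (stats::sd(tr$fitted_age) > 0) {
    stats::cor(tr$fitted_age, tr$chronological_age)
  } else NA_real_
  out <- list(clock = object,
              in_sample_r = r,
              in_sample_mae = mean(abs(tr$fitted_age - tr$chronological_age)))
  class(out) <- "summary.epiclock"
  out
}

#' @export
print.summary.epiclock <- function(x, ...) {
  print(x$clock)
  cat(sprintf("  in-sample: r = %.3f, MAE = %.2f years\n",
              x$in_sample_r, x$in_sample_mae))
  invisible(x)
}

#' @export
coef.epiclock <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Predict epigenetic age
#'
#' Applies the clock's stored normalization constants and weights:
#' epigenetic age = intercept + sum of weight x z-scored methylation.
#' Every weighted site must be present in the new matrix.
#'
#' @param object An \code{\link{epiclock}} model.
#' @param newdata A \code{\link{meth_matrix}} or sites x samples matrix.
#' @param ... Unused.
#' @return Named numeric vector of epigenetic ages (years), one per sample.
#' @export
predict.epiclock <- function(object, newdata, ...) {
  xp <- as_predictor_matrix(newdata) # samples x sites
  if (object$n_nonzero == 0) {
    return(stats::setNames(rep(object$intercept, nrow(xp)), rownames(xp)))
  }
  miss <- setdiff(names(object$weights), colnames(xp))
  if (length(miss)) {
    stop_param("newdata lacks %d weighted site(s) (e.g. %s)",
               length(miss), miss[1])
  }
  z <- (xp[, names(object$weights), drop = FALSE] -
          rep(object$center, each = nrow(xp))) /
    rep(object$scale, each = nrow(xp))
  stats::setNames(as.numeric(object$intercept + z %*% object$weights),
                  rownames(xp))
}

#' Predict epigenetic age as a prediction table
#'
#' @param model An \code{\link{epiclock}}.
#' @param x New methylation data (see \code{\link{predict.epiclock}}).
#' @param chronological_age Optional ages to carry along.
#' @return data.frame with \code{subject_id}, \code{chronological_age} and
#'   \code{epigenetic_age}.
#' @export
predict_age <- function(model, x, chronological_age = NULL) {
  pred <- predict(model, x)
  data.frame(subject_id = names(pred),
             chronological_age = if (is.null(chronological_age))
               NA_real_ else chronological_age,
             epigenetic_age = as.numeric(pred),
             stringsAsFactors = FALSE)
}

#' Leave-one-out cross-validated epigenetic ages
#'
#' For each subject the entire fitting pipeline — normalization constants,
#' internal lambda cross-validation, elastic-net coefficients — is rerun on
#' the remaining n-1 subjects, and the held-out subject's age is predicted
#' by that model, so no subject ever contributes to its own estimate.
#'
#' @inheritParams epiclock
#' @return An object of class \code{"epiclock_cv"}: a data.frame with
#'   \code{subject_id}, \code{chronological_age}, \code{epigenetic_age},
#'   plus per-fold attributes \code{fold_lambda} and \code{fold_nonzero}.
#' @export
loocv_clock <- function(x, age, alpha = 0.5, nfolds = 10, lambda = NULL,
                        seed = NULL, nlambda = 100,
                        lambda.min.ratio = 1e-4) {
  frac <- if (inherits(x, "meth_matrix")) x$fraction else as.matrix(x)
  if (anyNA(frac)) stop_param("matrix has missing cells; filter first")
  n <- ncol(frac)
  if (n < 3) stop_param("leave-one-out needs at least 3 samples")
  if (length(age) != n) stop_param("length(age) != number of samples")
  samples <- colnames(frac)
  if (is.null(samples)) samples <- sprintf("sample%d", seq_len(n))
  pred <- numeric(n)
  fold_lambda <- numeric(n)
  fold_nzero <- integer(n)
  for (i in seq_len(n)) {
    fit <- epiclock(frac[, -i, drop = FALSE], age[-i], alpha = alpha,
                    nfolds = nfolds, lambda = lambda,
                    seed = if (is.null(seed)) NULL else seed + i,
                    nlambda = nlambda, lambda.min.ratio = lambda.min.ratio)
    pred[i] <- predict(fit, frac[, i, drop = FALSE])
    fold_lambda[i] <- fit$lambda
    fold_nzero[i] <- fit$n_nonzero
  }
  out <- data.frame(subject_id = samples,
                    chronological_age = age,
                    epigenetic_age = pred,
                    stringsAsFactors = FALSE)
  attr(out, "fold_lambda") <- fold_lambda
  attr(out, "fold_nonzero") <- fold_nzero
  class(out) <- c("epiclock_cv", "data.frame")
  out
}

#' @export
summary.epiclock_cv <- function(object, ...) {
  r <- stats::cor(object$epigenetic_age, object$chronological_age)
  mae <- mean(abs(object$epigenetic_age - object$chronological_age))
  out <- list(n = nrow(object), r = r, mae = mae,
              median_nonzero = stats::median(attr(object, "fold_nonzero")))
  class(out) <- "summary.epiclock_cv"
  out
}

#' @export
print.summary.epiclock_cv <- function(x, ...) {
  cat("Leave-one-out epigenetic age estimates\n")
  cat(sprintf("  n = %d, r(epigenetic, chronological) = %.3f, MAE = %.2f y\n",
              x$n, x$r, x$mae))
  cat(sprintf("  median weighted sites per fold: %.0f\n", x$median_nonzero))
  invisible(x)
}

#' @export
print.epiclock_cv <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Residual age discrepancies from cross-validated predictions
#'
#' \code{method = "diff"} returns the raw delta age (epigenetic minus
#' chronological); \code{method = "resid"} the unstandardized residuals of
#' the cohort-level OLS of epigenetic on chronological age.
#'
#' @param object An \code{\link{loocv_clock}} result.
#' @param method \code{"diff"} or \code{"resid"}.
#' @param ... Unused.
#' @export
residuals.epiclock_cv <- function(object, method = c("diff", "resid"), ...) {
  method <- match.arg(method)
  if (method == "diff") {
    delta_diff(object$epigenetic_age, object$chronological_age)
  } else {
    delta_resid(object)
  }
}

#' @export
plot.epiclock_cv <- function(x, ...) {
  plot(x$chronological_age, x$epigenetic_age,
       xlab = "Chronological age (years)",
       ylab = "Epigenetic age (years)", pch = 19, col = "grey30", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
plot.epiclock <- function(x, ...) {
  plot(x$training$chronological_age, x$training$fitted_age,
       xlab = "Chronological age (years)",
       ylab = "Fitted epigenetic age (years)", pch = 19, col = "grey30", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

CLOCK_FORMAT_VERSION <- 1L

#' Serialize / deserialize a fitted clock
#'
#' The clock file is a TSV (site, weight, center, scale) preceded by
#' \code{#}-prefixed header lines carrying the format version, intercept,
#' alpha, lambda and seed. \code{read_clock(write_clock(m, p))} recovers
#' the model's predictive content exactly.
#'
#' @param model An \code{\link{epiclock}}.
#' @param path File path.
#' @return \code{write_clock}: the path, invisibly. \code{read_clock}: an
#'   \code{epiclock} object (without training data or CV curve).
#' @export
write_clock <- function(model, path) {
  stopifnot(inherits(model, "epiclock"))
  header <- c(
    sprintf("#epiage_clock\tversion=%d", CLOCK_FORMAT_VERSION),
    sprintf("#intercept\t%s", format(model$intercept, digits = 17)),
    sprintf("#alpha\t%s", format(model$alpha, digits = 17)),
    sprintf("#lambda\t%s", format(model$lambda, digits = 17)),
    sprintf("#seed\t%s", if (is.null(model$seed)) "NA" else model$seed),
    "site\tweight\tcenter\tscale")
  rows <- if (model$n_nonzero > 0) {
    sprintf("%s\t%s\t%s\t%s", names(model$weights),
            format(model$weights, digits = 17),
            format(model$center, digits = 17),
            format(model$scale, digits = 17))
  } else character(0)
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#epiage_clock")) {
    stop_param("'%s' is not a clock file", path)
  }
  version <- as.integer(sub(".*version=", "", lines[1]))
  if (!identical(version, CLOCK_FORMAT_VERSION)) {
    stop_param("clock file version %s not supported (expected %d)",
               version, CLOCK_FORMAT_VERSION)
  }
  get_field <- function(key) {
    ln <- grep(paste0("^#", key, "\t"), lines, value = TRUE)[1]
    strsplit(ln, "\t")[[1]][2]
  }
  intercept <- as.numeric(get_field("intercept"))
  alpha <- as.numeric(get_field("alpha"))
  lambda <- as.numeric(get_field("lambda"))
  seed_chr <- get_field("seed")
  body_at <- which(!startsWith(lines, "#"))[1]
  tab <- utils::read.table(text = lines[seq(body_at, length(lines))],
                           header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric",
                                          "numeric", "numeric"),
                           stringsAsFactors = FALSE)
  weights <- stats::setNames(tab$weight, tab$site)
  structure(list(intercept = intercept,
                 weights = weights,
                 center = stats::setNames(tab$center, tab$site),
                 scale = stats::setNames(tab$scale, tab$site),
                 alpha = alpha, lambda = lambda,
                 nfolds = NA_integer_,
                 seed = if (seed_chr == "NA") NULL else as.integer(seed_chr),
                 n_nonzero = length(weights),
                 n_train = NA_integer_,
                 n_candidate_sites = NA_integer_,
                 training = data.frame(chronological_age = numeric(0),
                                       fitted_age = numeric(0))),
            class = "epiclock")
}
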