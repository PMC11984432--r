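#' Specify a synthetic baboon cohort
#'
#' Describes the demographic composition of a simulated captive cohort:
#' size, age range, sex ratio, and rearing history (mother- vs
#' nursery-reared, with an optional number of subjects of unknown rearing).
#' Defaults mirror a colony of 140 olive baboons aged 1.17-19.33 years,
#' 118 female / 22 male, with 86 nursery-reared and 52 mother-reared among
#' the 138 subjects of known rearing history.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param age_range Numeric length-2, minimum and maximum age in years.
#' @param female_fraction Proportion of females.
#' @param nursery_fraction Proportion nursery-reared among subjects with a
#'   known rearing history.
#' @param unknown_rearing_count Number of subjects with unknown rearing.
#' @param age_distribution \code{"uniform"} draws ages uniformly over
#'   \code{age_range}; \code{"grouped"} draws from a four-bin mixture with
#'   weights proportional to the 13/49/58/20 juvenile / young-adult /
#'   older-adult / geriatric design.
#' @param seed Integer seed, or NULL to use the current RNG stream.
#' @return An object of class \code{"cohort_spec"}.
#' @export
cohort_spec <- function(n_subjects = 140,
                        age_range = c(1.17, 19.33),
                        female_fraction = 118 / 140,
                        nursery_fraction = 86 / 138,
                        unknown_rearing_count = 2,
                        age_distribution = c("uniform", "grouped"),
                        seed = NULL) {
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2)
  check_fraction(female_fraction, "female_fraction")
  check_fraction(nursery_fraction, "nursery_fraction")
  unknown_rearing_count <- check_count(unknown_rearing_count,
                                       "unknown_rearing_count")
  if (length(age_range) != 2 || age_range[1] >= age_range[2] ||
      age_range[1] < 0) {
    stop_param("'age_range' must be (min, max) with 0 <= min < max")
  }
  if (unknown_rearing_count > n_subjects) {
    stop_param("'unknown_rearing_count' exceeds 'n_subjects'")
  }
  structure(list(n_subjects = n_subjects,
                 age_range = as.numeric(age_range),
                 female_fraction = female_fraction,
                 nursery_fraction = nursery_fraction,
                 unknown_rearing_count = unknown_rearing_count,
                 age_distribution = match.arg(age_distribution),
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate a cohort table
#'
#' Draws a subject table from a \code{\link{cohort_spec}}. Sex and rearing
#' counts are fixed at the rounded expected values and assigned to subjects
#' in random order, so the realised composition matches the specification
#' exactly; ages are drawn from the requested distribution.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A data.frame with columns \code{subject_id}, \code{sex}
#'   (female/male), \code{rearing} (mother/nursery/unknown), \code{age}
#'   (years) and \code{age_group} (see \code{\link{assign_age_group}}).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    n_f <- round(n * spec$female_fraction)
    sex <- sample(rep(c("female", "male"), c(n_f, n - n_f)))
    n_known <- n - spec$unknown_rearing_count
    n_nursery <- round(n_known * spec$nursery_fraction)
    rearing <- sample(rep(c("nursery", "mother", "unknown"),
                          c(n_nursery, n_known - n_nursery,
                            spec$unknown_rearing_count)))
    age <- if (spec$age_distribution == "uniform") {
      stats::runif(n, spec$age_range[1], spec$age_range[2])
    } else {
      draw_grouped_ages(n, spec$age_range)
    }
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               sex = factor(sex, levels = c("female", "male")),
               rearing = factor(rearing,
                                levels = c("mother", "nursery", "unknown")),
               age = age,
               age_group = assign_age_group(age),
               stringsAsFactors = FALSE)
  })
}

# Four-bin age mixture: bins [min,5), [5,10), [10,15), [15,max], weights
# proportional to the 13/49/58/20 unbalanced design.
draw_grouped_ages <- function(n, age_range) {
  edges <- c(age_range[1], 5, 10, 15, age_range[2])
  bin <- sample(4, n, replace = TRUE, prob = c(13, 49, 58, 20) / 140)
  stats::runif(n, edges[bin], edges[bin + 1])
}

#' Specify the distribution of biological-age offsets
#'
#' Each subject carries a latent delta age: the signed gap between its
#' biological (methylation-driving) age and its chronological age. The
#' default SD of 1.5 years is consistent with observed per-subject delta
#' ages spanning roughly -6.5 to +4 years in a cohort of 140.
#'
#' @param delta_sd Standard deviation of the delta-age distribution (years).
#' @param delta_age_distribution Distribution family; only \code{"normal"}
#'   is currently implemented.
#' @param seed Integer seed or NULL.
#' @return An object of class \code{"aging_rate_spec"}.
#' @export
aging_rate_spec <- function(delta_sd = 1.5,
                            delta_age_distribution = "normal",
                            seed = NULL) {
  if (!is.numeric(delta_sd) || length(delta_sd) != 1 || delta_sd < 0) {
    stop_param("'delta_sd' must be a single number >= 0")
  }
  delta_age_distribution <- match.arg(delta_age_distribution, "normal")
  structure(list(delta_sd = delta_sd,
                 delta_age_distribution = delta_age_distribution,
                 seed = seed),
            class = "aging_rate_spec")
}

#' Simulate per-subject biological ages
#'
#' Adds a latent delta age to each subject's chronological age. The result
#' is the ground truth that the epigenetic clock is expected to recover:
#' methylation is generated from biological, not chronological, age.
#'
#' @param cohort A cohort table from \code{\link{simulate_cohort}}.
#' @param spec An \code{\link{aging_rate_spec}}.
#' @return A data.frame with \code{subject_id}, \code{age},
#'   \code{delta_true} and \code{biological_age} (floored at 0).
#' @export
simulate_biological_ages <- function(cohort, spec = aging_rate_spec()) {
  stopifnot(inherits(spec, "aging_rate_spec"), nrow(cohort) >= 1)
  with_seed(spec$seed, {
    delta <- stats::rnorm(nrow(cohort), 0, spec$delta_sd)
    data.frame(subject_id = cohort$subject_id,
               age = cohort$age,
               delta_true = delta,
               biological_age = pmax(cohort$age + delta, 0),
               stringsAsFactors = FALSE)
  })
}

#' Specify a synthetic RRBS methylation matrix
#'
#' Describes the mixture of CpG site classes that the site-exclusion
#' cascade and the clock are designed to confront: age-informative sites
#' whose expected methylation fraction moves linearly with biological age;
#' invariant sites pinned near 0 or 1; polymorphic sites whose apparent
#' fraction is genotype- rather than age-driven; background sites with
#' age-independent intermediate methylation; and sites carrying missing
#' calls in some subjects.
#'
#' Age slopes: when \code{age_slope_range} is non-negative it is read as a
#' magnitude range and each age-informative site receives a random sign;
#' when the lower bound is negative, slopes are drawn uniformly over the
#' signed range as given.
#'
#' @param n_sites Total number of CpG sites.
#' @param n_age_sites Number of age-informative sites.
#' @param age_slope_range Length-2 numeric, methylation fraction per year.
#' @param baseline_range Admissible range for expected fractions; baselines
#'   are drawn so the linear trend stays inside it over the whole age range.
#' @param noise_sd SD of per-cell Gaussian jitter on the true fraction,
#'   applied before binomial read sampling.
#' @param n_invariant_low,n_invariant_high Counts of sites with mean
#'   methylation < 0.1 and > 0.9.
#' @param n_polymorphic Count of genotype-driven sites (listed in the BED
#'   exclusion sidecar).
#' @param missing_rate Proportion of sites that carry at least one missing
#'   call (depth 0) in some subject.
#' @param coverage_mean Mean read depth; per-cell depth is Poisson with
#'   this mean, floored at 1.
#' @param seed Integer seed or NULL.
#' @return An object of class \code{"methylation_sim_spec"}.
#' @export
methylation_sim_spec <- function(n_sites = 2000,
                                 n_age_sites = 150,
                                 age_slope_range = c(0.02, 0.04),
                                 baseline_range = c(0.05, 0.95),
                                 noise_sd = 0.02,
                                 n_invariant_low = 200,
                                 n_invariant_high = 200,
                                 n_polymorphic = 100,
                                 missing_rate = 0.05,
                                 coverage_mean = 20,
                                 seed = NULL) {
  n_sites <- check_count(n_sites, "n_sites", min = 1)
  n_age_sites <- check_count(n_age_sites, "n_age_sites")
  n_invariant_low <- check_count(n_invariant_low, "n_invariant_low")
  n_invariant_high <- check_count(n_invariant_high, "n_invariant_high")
  n_polymorphic <- check_count(n_polymorphic, "n_polymorphic")
  check_fraction(missing_rate, "missing_rate")
  if (n_age_sites + n_invariant_low + n_invariant_high + n_polymorphic >
      n_sites) {
    stop_param("site class counts exceed 'n_sites'")
  }
  if (length(age_slope_range) != 2 ||
      age_slope_range[1] > age_slope_range[2]) {
    stop_param("'age_slope_range' must be (min, max) with min <= max")
  }
  if (length(baseline_range) != 2 || baseline_range[1] < 0 ||
      baseline_range[2] > 1 || baseline_range[1] >= baseline_range[2]) {
    stop_param("'baseline_range' must be (min, max) inside [0, 1]")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_param("'noise_sd' must be >= 0")
  }
  if (!is.numeric(coverage_mean) || coverage_mean <= 0) {
    stop_param("'coverage_mean' must be > 0")
  }
  structure(list(n_sites = n_sites, n_age_sites = n_age_sites,
                 age_slope_range = as.numeric(age_slope_range),
                 baseline_range = as.numeric(baseline_range),
                 noise_sd = noise_sd,
                 n_invariant_low = n_invariant_low,
                 n_invariant_high = n_invariant_high,
                 n_polymorphic = n_polymorphic,
                 missing_rate = missing_rate,
                 coverage_mean = coverage_mean,
                 seed = seed),
            class = "methylation_sim_spec")
}

#' Simulate an RRBS methylation matrix with a known site truth table
#'
#' @param cohort Cohort table from \code{\link{simulate_cohort}}.
#' @param biological_ages Output of \code{\link{simulate_biological_ages}}
#'   (defaults to delta 0, i.e. biological = chronological age).
#' @param spec A \code{\link{methylation_sim_spec}}.
#' @return A list with elements \code{matrix} (a \code{\link{meth_matrix}}),
#'   \code{truth} (per-site class, baseline, slope and missingness flag)
#'   and \code{snp_bed} (0-based half-open BED intervals covering the
#'   polymorphic sites).
#' @export
simulate_methylation <- function(cohort, biological_ages = NULL,
                                 spec = methylation_sim_spec()) {
  stopifnot(inherits(spec, "methylation_sim_spec"))
  if (is.null(biological_ages)) {
    biological_ages <- data.frame(subject_id = cohort$subject_id,
                                  biological_age = cohort$age)
  }
  bio <- biological_ages$biological_age[
    match(cohort$subject_id, biological_ages$subject_id)]
  if (anyNA(bio)) stop_param("biological_ages must cover every subject")
  max_slope <- max(abs(spec$age_slope_range))
  span <- diff(spec$baseline_range) - max_slope * max(bio)
  if (span <= 0) {
    stop_param(paste("age slopes up to %.3f/yr leave no admissible baseline",
                     "within [%.2f, %.2f] over ages up to %.1f"),
               max_slope, spec$baseline_range[1], spec$baseline_range[2],
               max(bio))
  }
  with_seed(spec$seed, {
    n <- nrow(cohort)
    m <- spec$n_sites
    cls <- rep("background", m)
    idx <- sample(m) # random placement of classes along the site list
    k <- 0
    take <- function(count) {
      out <- idx[k + seq_len(count)]
      k <<- k + count
      out
    }
    i_age <- take(spec$n_age_sites)
    i_low <- take(spec$n_invariant_low)
    i_high <- take(spec$n_invariant_high)
    i_poly <- take(spec$n_polymorphic)
    cls[i_age] <- "age"
    cls[i_low] <- "invariant_low"
    cls[i_high] <- "invariant_high"
    cls[i_poly] <- "polymorphic"

    chrom <- paste0("chr", sample(20, m, replace = TRUE))
    pos <- integer(m)
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      pos[sel] <- sample(1e7L, sum(sel))
    }
    ord <- order(chrom, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; cls <- cls[ord]

    slope <- numeric(m)
    baseline <- numeric(m)
    is_age <- cls == "age"
    sr <- spec$age_slope_range
    slope[is_age] <- if (sr[1] >= 0) {
      stats::runif(sum(is_age), sr[1], sr[2]) *
        sample(c(-1, 1), sum(is_age), replace = TRUE)
    } else {
      stats::runif(sum(is_age), sr[1], sr[2])
    }
    # baseline drawn so baseline + slope * age stays inside baseline_range
    lo <- ifelse(slope >= 0, spec$baseline_range[1],
                 spec$baseline_range[1] - slope * max(bio))
    hi <- ifelse(slope >= 0, spec$baseline_range[2] - slope * max(bio),
                 spec$baseline_range[2])
    baseline[is_age] <- stats::runif(sum(is_age), lo[is_age], hi[is_age])
    baseline[cls == "background"] <-
      stats::runif(sum(cls == "background"), 0.15, 0.85)
    baseline[cls == "invariant_low"] <-
      stats::runif(sum(cls == "invariant_low"), 0.01, 0.08)
    baseline[cls == "invariant_high"] <-
      stats::runif(sum(cls == "invariant_high"), 0.92, 0.99)

    p <- matrix(baseline, m, n) + outer(slope, bio)
    # polymorphic sites: per-subject genotype fraction {0, 0.5, 1} under HWE
    if (length(i_poly) > 0) {
      poly_rows <- which(cls == "polymorphic")
      maf <- stats::runif(length(poly_rows), 0.2, 0.8)
      p[poly_rows, ] <- matrix(
        stats::rbinom(length(poly_rows) * n, 2, rep(maf, n)) / 2,
        length(poly_rows), n)
    }
    if (spec$noise_sd > 0) {
      p <- p + matrix(stats::rnorm(m * n, 0, spec$noise_sd), m, n)
    }
    p <- pmin(pmax(p, 0), 1)

    depth <- matrix(pmax(stats::rpois(m * n, spec$coverage_mean), 1L), m, n)
    meth <- matrix(stats::rbinom(m * n, as.vector(depth), as.vector(p)),
                   m, n)
    frac <- meth / depth

    has_missing <- rep(FALSE, m)
    n_missing_sites <- round(spec$missing_rate * m)
    if (n_missing_sites > 0) {
      miss_sites <- sample(m, n_missing_sites)
      has_missing[miss_sites] <- TRUE
      for (s in miss_sites) {
        ncells <- 1 + stats::rbinom(1, n - 1, 0.03)
        cells <- sample(n, ncells)
        depth[s, cells] <- 0L
        frac[s, cells] <- NA_real_
      }
    }

    sites <- data.frame(chrom = chrom, pos = pos, strand = "*",
                        stringsAsFactors = FALSE)
    mm <- meth_matrix(frac, depth, sites, samples = cohort$subject_id)
    truth <- data.frame(chrom = chrom, pos = pos, class = cls,
                        baseline = baseline, slope = slope,
                        has_missing = has_missing,
                        stringsAsFactors = FALSE)
    poly_rows <- which(cls == "polymorphic")
    snp_bed <- data.frame(chrom = chrom[poly_rows],
                          start = pos[poly_rows] - 1L,
                          end = pos[poly_rows],
                          stringsAsFactors = FALSE)
    snp_bed <- snp_bed[order(snp_bed$chrom, snp_bed$start), , drop = FALSE]
    rownames(snp_bed) <- NULL
    list(matrix = mm, truth = truth, snp_bed = snp_bed)
  })
}

#' Specify synthetic behavior observations
#'
#' Latent per-subject walking speed and fine-motor rate are linear in age
#' and sex (treatment coding, female reference) with Gaussian subject-level
#' noise; observed walking bouts and Brinkman-board trials scatter around
#' the latent values. Defaults encode the published cohort effects: walking
#' speed falls 0.009 m/s per year of age with a +0.103 m/s male effect
#' around a 0.70 m/s intercept; the fine-motor retrieval rate falls
#' 0.014 raisins/s per year with a -0.19 raisins/s male effect around a
#' 0.60 raisins/s intercept (chosen so sex-specific cohort means land near
#' the published 0.46 female / 0.28 male raisins/s). Noise SDs are set so
#' the age+sex+rearing regression attains adjusted R-squared near 0.261
#' (speed, n = 129) and 0.73 (motor, n = 38).
#'
#' @param speed_intercept,speed_age_slope,speed_male_effect,speed_noise_sd
#'   Walking-speed model parameters (m/s; slope in m/s per year).
#' @param motor_intercept,motor_age_slope,motor_male_effect,motor_noise_sd
#'   Fine-motor model parameters (raisins/s; slope per year).
#' @param n_bouts_min Minimum walking bouts recorded per subject.
#' @param bout_noise_sd SD of bout-level speed scatter (m/s).
#' @param trial_noise_sd SD of trial-level rate scatter (raisins/s).
#' @param seed Integer seed or NULL.
#' @return An object of class \code{"behavior_sim_spec"}.
#' @export
behavior_sim_spec <- function(speed_intercept = 0.70,
                              speed_age_slope = -0.009,
                              speed_male_effect = 0.103,
                              speed_noise_sd = 0.098,
                              motor_intercept = 0.60,
                              motor_age_slope = -0.014,
                              motor_male_effect = -0.19,
                              motor_noise_sd = 0.068,
                              n_bouts_min = 10,
                              bout_noise_sd = 0.05,
                              trial_noise_sd = 0.03,
                              seed = NULL) {
  for (nm in c("speed_noise_sd", "motor_noise_sd", "bout_noise_sd",
               "trial_noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v < 0) {
      stop_param("'%s' must be a single number >= 0", nm)
    }
  }
  n_bouts_min <- check_count(n_bouts_min, "n_bouts_min", min = 1)
  structure(list(speed_intercept = speed_intercept,
                 speed_age_slope = speed_age_slope,
                 speed_male_effect = speed_male_effect,
                 speed_noise_sd = speed_noise_sd,
                 motor_intercept = motor_intercept,
                 motor_age_slope = motor_age_slope,
                 motor_male_effect = motor_male_effect,
                 motor_noise_sd = motor_noise_sd,
                 n_bouts_min = n_bouts_min,
                 bout_noise_sd = bout_noise_sd,
                 trial_noise_sd = trial_noise_sd,
                 seed = seed),
            class = "behavior_sim_spec")
}

#' Simulate walking bouts and fine-motor trials
#'
#' @param cohort Cohort table from \code{\link{simulate_cohort}}.
#' @param spec A \code{\link{behavior_sim_spec}}.
#' @return A list with \code{bouts} (subject_id, distance in m, time in s),
#'   \code{trials} (subject_id, session, trial, raisins, elapsed in s,
#'   failed) and \code{truth} (per-subject latent speed and motor rate).
#' @export
simulate_behavior <- function(cohort, spec = behavior_sim_spec()) {
  stopifnot(inherits(spec, "behavior_sim_spec"))
  with_seed(spec$seed, {
    n <- nrow(cohort)
    male <- as.numeric(cohort$sex == "male")
    latent_speed <- pmax(
      spec$speed_intercept + spec$speed_age_slope * cohort$age +
        spec$speed_male_effect * male +
        stats::rnorm(n, 0, spec$speed_noise_sd), 0.05)
    latent_rate <- pmax(
      spec$motor_intercept + spec$motor_age_slope * cohort$age +
        spec$motor_male_effect * male +
        stats::rnorm(n, 0, spec$motor_noise_sd), 0.02)

    n_bouts <- spec$n_bouts_min + stats::rpois(n, 2)
    bouts <- data.frame(
      subject_id = rep(cohort$subject_id, n_bouts),
      distance = stats::runif(sum(n_bouts), 5, 20))
    bout_speed <- pmax(rep(latent_speed, n_bouts) +
                         stats::rnorm(sum(n_bouts), 0, spec$bout_noise_sd),
                       0.05)
    bouts$time <- bouts$distance / bout_speed

    # 2 sessions x 4 trials of 12 raisins; a trial fails at the 180 s cap
    n_trials <- 8L
    trials <- data.frame(
      subject_id = rep(cohort$subject_id, each = n_trials),
      session = rep(rep(1:2, each = 4), n),
      trial = rep(rep(1:4, 2), n))
    trial_rate <- pmax(rep(latent_rate, each = n_trials) +
                         stats::rnorm(n * n_trials, 0, spec$trial_noise_sd),
                       0.02)
    elapsed <- 12 / trial_rate
    failed <- elapsed > 180
    trials$raisins <- ifelse(failed, pmin(floor(trial_rate * 180), 12), 12L)
    trials$elapsed <- ifelse(failed, 180, elapsed)
    trials$failed <- failed

    truth <- data.frame(subject_id = cohort$subject_id,
                        latent_speed = latent_speed,
                        latent_rate = latent_rate,
                        stringsAsFactors = FALSE)
    list(bouts = bouts, trials = trials, truth = truth)
  })
}

#' Simulate a behavior study cohort with derived per-subject indicators
#'
#' Convenience wrapper reproducing the composition of the walking-speed
#' (n = 129, 109 female / 18 male among known-rearing subjects) or
#' fine-motor (n = 38, 27 female / 11 male) study samples, generating the
#' raw observations and reducing them to per-subject indicators ready for
#' \code{\link{fit_age_regression}}.
#'
#' @param n Number of subjects.
#' @param kind \code{"speed"} or \code{"motor"}.
#' @param seed Integer seed or NULL.
#' @param behavior_spec A \code{\link{behavior_sim_spec}}; its seed is
#'   derived from \code{seed} when NULL.
#' @return A data.frame of subjects with \code{age}, \code{sex},
#'   \code{rearing} and the outcome column (\code{speed} in m/s or
#'   \code{motor_rate} in raisins/s).
#' @export
simulate_behavior_study <- function(n = if (kind == "speed") 129 else 38,
                                    kind = c("speed", "motor"),
                                    seed = NULL,
                                    behavior_spec = behavior_sim_spec()) {
  kind <- match.arg(kind)
  female_fraction <- if (kind == "speed") 109 / 127 else 27 / 38
  cs <- cohort_spec(n_subjects = n, female_fraction = female_fraction,
                    unknown_rearing_count = 0, seed = seed)
  cohort <- simulate_cohort(cs)
  if (is.null(behavior_spec$seed) && !is.null(seed)) {
    behavior_spec$seed <- seed + 5e5L
  }
  beh <- simulate_behavior(cohort, behavior_spec)
  out <- cohort
  if (kind == "speed") {
    sp <- walking_speed(beh$bouts, min_bouts = behavior_spec$n_bouts_min)
    out$speed <- sp$speed[match(out$subject_id, sp$subject_id)]
  } else {
    mo <- motor_performance(beh$trials)
    out$motor_rate <- mo$rate[match(out$subject_id, mo$subject_id)]
  }
  out
}
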