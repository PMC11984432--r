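# Shared fixtures and independent brute-force oracles.

# Tiny meth_matrix built directly from a fraction matrix; depth defaults
# to a constant, with depth 0 wherever fraction is NA.
make_mm <- function(frac, depth = 20L, chrom = NULL, pos = NULL) {
  frac <- as.matrix(frac)
  m <- nrow(frac)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  d <- matrix(depth, m, ncol(frac))
  d[is.na(frac)] <- 0L
  if (is.null(colnames(frac))) {
    colnames(frac) <- sprintf("s%02d", seq_len(ncol(frac)))
  }
  meth_matrix(frac, d, data.frame(chrom = chrom, pos = pos),
              samples = colnames(frac))
}

random_mm <- function(n_sites = 100, n_samples = 20, missing_rate = 0.02,
                      seed = 1) {
  set.seed(seed)
  frac <- matrix(runif(n_sites * n_samples), n_sites, n_samples)
  depth <- matrix(rpois(n_sites * n_samples, 12) + 1L, n_sites, n_samples)
  miss <- matrix(runif(n_sites * n_samples) < missing_rate,
                 n_sites, n_samples)
  frac[miss] <- NA
  depth[miss] <- 0L
  chrom <- sample(paste0("chr", 1:3), n_sites, replace = TRUE)
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos[sel] <- sample(1e5L, sum(sel))
  }
  colnames(frac) <- sprintf("s%02d", seq_len(n_samples))
  meth_matrix(frac, depth, data.frame(chrom = chrom, pos = pos),
              samples = colnames(frac))
}

# Brute-force single-stage filter oracles: explicit per-site loops,
# independent of the vectorized implementation.
bf_keep_mean_meth <- function(mm, low = 0.1, high = 0.9) {
  keep <- logical(nrow(mm$fraction))
  for (i in seq_along(keep)) {
    v <- mm$fraction[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0) { keep[i] <- TRUE; next }
    mu <- sum(v) / length(v)
    keep[i] <- !(mu < low || mu > high)
  }
  keep
}

bf_keep_mean_depth <- function(mm, min_mean_depth = 5) {
  keep <- logical(nrow(mm$depth))
  for (i in seq_along(keep)) {
    keep[i] <- mean(mm$depth[i, ]) >= min_mean_depth
  }
  keep
}

bf_keep_complete <- function(mm) {
  keep <- logical(nrow(mm$fraction))
  for (i in seq_along(keep)) keep[i] <- !anyNA(mm$fraction[i, ])
  keep
}

bf_keep_not_in_bed <- function(mm, bed) {
  keep <- rep(TRUE, nrow(mm$fraction))
  for (i in seq_along(keep)) {
    p0 <- mm$sites$pos[i] - 1L # 0-based
    for (j in seq_len(nrow(bed))) {
      if (mm$sites$chrom[i] == bed$chrom[j] &&
          p0 >= bed$start[j] && p0 < bed$end[j]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

site_ids <- function(mm) rownames(mm$fraction)

# Closed-form OLS through the normal equations (independent of lm/glmnet).
bf_ols <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(crossprod(Xi), crossprod(Xi, y)))
}

# Delta-age records with prescribed category counts, used to rebuild
# published-style category tables.
records_from_counts <- function(n_decel, n_match, n_accel,
                                measure = "diff") {
  delta <- c(rep(-2, n_decel), rep(0, n_match), rep(2, n_accel))
  out <- data.frame(subject_id = sprintf("S%d", seq_along(delta)))
  out[[paste0("delta_", measure)]] <- delta
  out[[paste0("category_", measure)]] <- categorize_delta(delta)
  out
}
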