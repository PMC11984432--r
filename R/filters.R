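# Site-exclusion cascade applied to candidate clock CpGs.
#
# Boundary semantics are strict inequalities throughout: a site is dropped
# when its mean methylation is < low or > high, or its mean depth is < the
# minimum; values exactly at a threshold are retained.

subset_sites <- function(x, keep) {
  meth_matrix(x$fraction[keep, , drop = FALSE],
              x$depth[keep, , drop = FALSE],
              x$sites[keep, , drop = FALSE],
              samples = colnames(x$fraction))
}

#' Drop CpG sites at known polymorphic positions
#'
#' Genetic C>T variants are indistinguishable from bisulfite-converted
#' unmethylated cytosines, so CpGs overlapping known variants are removed
#' by position. Intervals follow the BED convention (0-based half-open);
#' site coordinates are 1-based, so a site at position p is excluded when
#' some interval satisfies start < p <= end.
#'
#' @param x A \code{\link{meth_matrix}}.
#' @param snp_positions data.frame with \code{chrom}, \code{start},
#'   \code{end} (BED intervals), or NULL/empty for a no-op.
#' @return A filtered \code{meth_matrix}.
#' @export
exclude_polymorphic <- function(x, snp_positions) {
  stopifnot(inherits(x, "meth_matrix"))
  if (is.null(snp_positions) || nrow(snp_positions) == 0) return(x)
  hit <- sites_in_bed(x$sites$chrom, x$sites$pos, snp_positions)
  subset_sites(x, !hit)
}

# 1-based positions vs 0-based half-open intervals, per chromosome.
sites_in_bed <- function(chrom, pos, bed) {
  hit <- logical(length(pos))
  for (ch in unique(bed$chrom)) {
    iv <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    # merge overlapping intervals so findInterval sees disjoint blocks
    o <- order(iv$start, iv$end)
    s <- iv$start[o]; e <- iv$end[o]
    ms <- s[1]; me <- e[1]; starts <- ends <- numeric(0)
    for (k in seq_along(s)[-1]) {
      if (s[k] <= me) me <- max(me, e[k]) else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- s[k]; me <- e[k]
      }
    }
    starts <- c(starts, ms); ends <- c(ends, me)
    zero_based <- pos[sel] - 1L
    blk <- findInterval(zero_based, starts)
    hit[sel] <- blk >= 1 & zero_based < ends[pmax(blk, 1)]
  }
  hit
}

#' Filter CpG sites by mean methylation level
#'
#' Retains informative sites: those whose across-sample mean methylation
#' (over non-missing cells) lies in [low, high]. Sites where every cell is
#' missing have an undefined mean and are passed through untouched (the
#' missing-data filter is responsible for them).
#'
#' @param x A \code{\link{meth_matrix}}.
#' @param low,high Retention bounds (defaults 0.1 and 0.9).
#' @return A filtered \code{meth_matrix}.
#' @export
filter_mean_methylation <- function(x, low = 0.1, high = 0.9) {
  stopifnot(inherits(x, "meth_matrix"), nrow(x$fraction) > 0)
  mu <- rowMeans(x$fraction, na.rm = TRUE)
  drop <- !is.nan(mu) & (mu < low | mu > high)
  subset_sites(x, !drop)
}

#' Filter CpG sites by mean depth of coverage
#'
#' @param x A \code{\link{meth_matrix}}.
#' @param min_mean_depth Sites with mean read depth (over all samples,
#'   missing cells counting as depth 0) below this are dropped; exactly at
#'   the threshold is retained. Default 5.
#' @return A filtered \code{meth_matrix}.
#' @export
filter_mean_depth <- function(x, min_mean_depth = 5) {
  stopifnot(inherits(x, "meth_matrix"))
  subset_sites(x, rowMeans(x$depth) >= min_mean_depth)
}

#' Drop CpG sites with missing data in any sample
#'
#' @param x A \code{\link{meth_matrix}}.
#' @return A \code{meth_matrix} with complete sites only.
#' @export
filter_missing <- function(x) {
  stopifnot(inherits(x, "meth_matrix"))
  subset_sites(x, rowSums(is.na(x$fraction)) == 0)
}

#' Run the full site-exclusion cascade
#'
#' Applies, in order: polymorphic-position exclusion, mean-methylation
#' filter, mean-depth filter, missing-data filter. Each stage's removal
#' count is relative to the previous stage's survivors, so the counts plus
#' the retained total reconstruct the input size exactly.
#'
#' @param x A \code{\link{meth_matrix}}.
#' @param snp_positions BED-style intervals for
#'   \code{\link{exclude_polymorphic}} (NULL skips that stage).
#' @param low,high,min_mean_depth Thresholds passed to the stage filters.
#' @return A list with \code{matrix} (the filtered \code{meth_matrix}) and
#'   \code{report}, a \code{filter_report} of per-stage removal counts.
#' @export
run_filter_cascade <- function(x, snp_positions = NULL,
                               low = 0.1, high = 0.9, min_mean_depth = 5) {
  stopifnot(inherits(x, "meth_matrix"))
  n0 <- nrow(x$fraction)
  x1 <- exclude_polymorphic(x, snp_positions)
  x2 <- filter_mean_methylation(x1, low = low, high = high)
  x3 <- filter_mean_depth(x2, min_mean_depth = min_mean_depth)
  x4 <- filter_missing(x3)
  report <- structure(list(
    n_input_sites = n0,
    n_removed_polymorphic = n0 - nrow(x1$fraction),
    n_removed_mean_low = n_low_count(x1, low),
    n_removed_mean_high = n_high_count(x1, high),
    n_removed_depth = nrow(x2$fraction) - nrow(x3$fraction),
    n_removed_missing = nrow(x3$fraction) - nrow(x4$fraction),
    n_retained = nrow(x4$fraction)), class = "filter_report")
  list(matrix = x4, report = report)
}

n_low_count <- function(x, low) {
  mu <- rowMeans(x$fraction, na.rm = TRUE)
  sum(!is.nan(mu) & mu < low)
}

n_high_count <- function(x, high) {
  mu <- rowMeans(x$fraction, na.rm = TRUE)
  sum(!is.nan(mu) & mu > high)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("CpG site-exclusion cascade\n")
  cat(sprintf("  input sites:          %d\n", x$n_input_sites))
  cat(sprintf("  - polymorphic:        %d\n", x$n_removed_polymorphic))
  cat(sprintf("  - mean methylation <: %d\n", x$n_removed_mean_low))
  cat(sprintf("  - mean methylation >: %d\n", x$n_removed_mean_high))
  cat(sprintf("  - mean depth:         %d\n", x$n_removed_depth))
  cat(sprintf("  - missing data:       %d\n", x$n_removed_missing))
  cat(sprintf("  retained:             %d\n", x$n_retained))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(stage = names(unclass(x)), count = unlist(unclass(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}
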