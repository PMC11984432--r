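#' Construct a methylation matrix
#'
#' A \code{meth_matrix} holds per-site, per-sample methylation fractions
#' together with read depth and genomic site coordinates. Sites are keyed
#' by (chromosome, 1-based position); cells with depth 0 are missing
#' (fraction NA).
#'
#' @param fraction Numeric matrix, sites x samples, values in [0,1] or NA.
#' @param depth Integer matrix of read depths, same shape.
#' @param sites data.frame with columns \code{chrom}, \code{pos} and
#'   optionally \code{strand}; one row per site.
#' @param samples Character vector of sample (subject) identifiers.
#' @return An object of class \code{"meth_matrix"}.
#' @export
meth_matrix <- function(fraction, depth, sites, samples = colnames(fraction)) {
  fraction <- as.matrix(fraction)
  depth <- as.matrix(depth)
  if (!all(dim(fraction) == dim(depth))) {
    stop_param("fraction and depth dimensions differ")
  }
  if (nrow(sites) != nrow(fraction)) {
    stop_param("sites table has %d rows but matrix has %d sites",
               nrow(sites), nrow(fraction))
  }
  if (is.null(samples)) samples <- sprintf("sample%d", seq_len(ncol(fraction)))
  if (length(samples) != ncol(fraction)) {
    stop_param("sample ids do not match matrix columns")
  }
  if (is.null(sites$strand)) sites$strand <- "*"
  ids <- site_id(sites$chrom, sites$pos)
  if (anyDuplicated(ids)) {
    stop_param("duplicate site (chromosome, position) pairs")
  }
  bad <- fraction[!is.na(fraction)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1)) {
    stop_param("methylation fractions must lie in [0, 1]")
  }
  if (any(is.na(fraction) & depth > 0)) {
    stop_param("fraction missing where depth > 0")
  }
  if (any(!is.na(fraction) & depth == 0)) {
    stop_param("fraction present where depth is 0")
  }
  dimnames(fraction) <- list(ids, samples)
  dimnames(depth) <- list(ids, samples)
  structure(list(fraction = fraction, depth = depth,
                 sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                                    strand = sites$strand,
                                    stringsAsFactors = FALSE)),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d CpG sites x %d samples\n",
              nrow(x$fraction), ncol(x$fraction)))
  n_missing <- sum(is.na(x$fraction))
  cat(sprintf("  missing cells: %d (%.2f%%)\n", n_missing,
              100 * n_missing / length(x$fraction)))
  cat(sprintf("  mean depth: %.1f\n", mean(x$depth[x$depth > 0])))
  invisible(x)
}

#' @export
dim.meth_matrix <- function(x) dim(x$fraction)

#' Read Bismark-style coverage files into a methylation matrix
#'
#' Each file is a tab-separated table with columns chromosome, start
#' (1-based), end, methylation percentage, methylated count, unmethylated
#' count — the Bismark \code{coverage2cytosine}/\code{bismark2bedGraph}
#' coverage dialect. The methylation fraction is recomputed from the two
#' counts; sites observed in some samples but not others become missing
#' cells (depth 0).
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample identifiers; default: file base names.
#' @return A \code{\link{meth_matrix}} over the union of sites, ordered by
#'   chromosome then position.
#' @export
read_coverage_files <- function(paths,
                                sample_ids = sub("\\.[^.]*$", "",
                                                 basename(paths))) {
  if (length(paths) != length(sample_ids) || anyDuplicated(sample_ids)) {
    stop_param("need one unique sample id per file")
  }
  tabs <- lapply(seq_along(paths), function(i) {
    path <- paths[i]
    tab <- tryCatch(
      utils::read.table(path, sep = "\t", header = FALSE,
                        col.names = c("chrom", "start", "end", "pct",
                                      "meth", "unmeth"),
                        colClasses = c("character", "integer", "integer",
                                       "numeric", "integer", "integer")),
      error = function(e) {
        stop_param("malformed coverage file '%s': %s", path,
                   conditionMessage(e))
      })
    if (anyNA(tab$start) || anyNA(tab$meth) || anyNA(tab$unmeth)) {
      bad <- which(is.na(tab$start) | is.na(tab$meth) | is.na(tab$unmeth))[1]
      stop_param("malformed row %d in coverage file '%s'", bad, path)
    }
    if (anyDuplicated(site_id(tab$chrom, tab$start))) {
      dup <- site_id(tab$chrom, tab$start)
      stop_param("duplicate site %s in coverage file '%s'",
                 dup[duplicated(dup)][1], path)
    }
    tab
  })
  all_sites <- unique(do.call(rbind, lapply(tabs, function(t) {
    data.frame(chrom = t$chrom, pos = t$start, stringsAsFactors = FALSE)
  })))
  all_sites <- all_sites[order(all_sites$chrom, all_sites$pos), , drop = FALSE]
  ids <- site_id(all_sites$chrom, all_sites$pos)
  m <- nrow(all_sites)
  n <- length(paths)
  frac <- matrix(NA_real_, m, n)
  depth <- matrix(0L, m, n)
  for (i in seq_len(n)) {
    t <- tabs[[i]]
    j <- match(site_id(t$chrom, t$start), ids)
    d <- t$meth + t$unmeth
    depth[j, i] <- d
    frac[j, i] <- ifelse(d > 0, t$meth / d, NA_real_)
  }
  meth_matrix(frac, depth, all_sites, samples = sample_ids)
}

#' Write a methylation matrix as per-sample coverage files
#'
#' Inverse of \code{\link{read_coverage_files}}: one Bismark-coverage-style
#' TSV per sample, omitting missing cells.
#'
#' @param x A \code{\link{meth_matrix}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths (named by sample).
#' @export
write_coverage_files <- function(x, dir) {
  stopifnot(inherits(x, "meth_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- colnames(x$fraction)
  paths <- file.path(dir, paste0(samples, ".cov"))
  for (i in seq_along(samples)) {
    keep <- !is.na(x$fraction[, i])
    meth <- round(x$fraction[keep, i] * x$depth[keep, i])
    tab <- data.frame(chrom = x$sites$chrom[keep],
                      start = x$sites$pos[keep],
                      end = x$sites$pos[keep],
                      pct = 100 * x$fraction[keep, i],
                      meth = as.integer(meth),
                      unmeth = as.integer(x$depth[keep, i] - meth))
    utils::write.table(tab, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(stats::setNames(paths, samples))
}

#' Read a BED file of positions to exclude
#'
#' BED is 0-based half-open: an interval (start, end) covers 1-based
#' positions start+1 .. end.
#'
#' @param path Path to a 3+ column BED file.
#' @return data.frame with \code{chrom}, \code{start}, \code{end}.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop_param("BED file '%s' has fewer than 3 columns", path)
  data.frame(chrom = as.character(tab[[1]]), start = as.integer(tab[[2]]),
             end = as.integer(tab[[3]]), stringsAsFactors = FALSE)
}
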