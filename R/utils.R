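#' @keywords internal
#' @importFrom graphics plot abline
#' @importFrom stats coef predict residuals
"_PACKAGE"

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise RNG so there is a state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_param("'%s' must be a single number in [0, 1] (got %s)",
               name, paste(format(x), collapse = ","))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_param("'%s' must be an integer >= %d (got %s)",
               name, min, paste(format(x), collapse = ","))
  }
  invisible(as.integer(x))
}

site_id <- function(chrom, pos) paste0(chrom, ":", pos)
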