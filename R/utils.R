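#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so library code never perturbs a user's
#' random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Locate a packaged default data file under inst/extdata.
cvh8_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cvh8")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

# Scalar missingness test that treats NULL, NA and empty strings as missing.
is_blank <- function(x) {
  is.null(x) || length(x) == 0L || all(is.na(x)) ||
    (is.character(x) && all(!nzchar(x)))
}

# assert helper with sprintf-style message
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
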