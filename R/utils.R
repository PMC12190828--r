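#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rpois runif rexp rnorm quantile sd t.test kmeans
#'   prcomp optim median
#' @importFrom utils head tail read.csv write.csv write.table
NULL

# Derive a child seed from a global seed and a stable component tag.
# Keeps the result strictly below 2^31 so set.seed() accepts it.
tagSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 5381
  for (cp in utf8ToInt(tag)) h <- (h * 33 + cp) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# Stable short hash of an R object (config provenance); djb2 over the
# canonical JSON text, reported as 8 hex digits.
configHash <- function(x) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 15, force = TRUE)
  h <- 5381
  for (cp in utf8ToInt(as.character(txt))) h <- (h * 33 + cp) %% 2147483647
  sprintf("%08x", as.integer(h))
}

assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  x
}

assertNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%g, %g]", name, lower, upper),
         call. = FALSE)
  as.numeric(x)
}

assertCount <- function(x, name, lower = 0L) {
  x <- assertNumber(x, name, lower = lower)
  if (x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
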