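#' @useDynLib tsgcn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rexp qr sd cor quantile
#' @importFrom utils head tail modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population (ddof = 0) standard deviation
#'
#' All moment statistics in the featurization use population moments so that
#' the standard deviation is consistent with the moment-based skew.
#' @param x numeric vector.
#' @return scalar standard deviation with divisor `length(x)`.
#' @keywords internal
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Fisher-Pearson moment coefficient of skewness
#'
#' g1 = m3 / m2^(3/2) with biased (population) moments; defined as 0 when the
#' second moment vanishes (all values equal).
#' @param x numeric vector.
#' @return scalar skewness.
#' @keywords internal
skew_g1 <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

# Canonical JSON used for config hashing and byte-stable reports: keys sorted,
# no scientific notation surprises (digits = NA keeps full precision).
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v), method = "radix")]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA, null = "null")
}

hash_config <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(canonical_json(x)), tf)
  unname(tools::md5sum(tf))
}

stop_tsgcn <- function(...) stop(sprintf(...), call. = FALSE)

# Counter-based per-replicate seed derivation: reproducible and extensible,
# always within the 32-bit signed integer range and strictly positive.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483629) + 1L
}
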