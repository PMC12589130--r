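#' @useDynLib bmigap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov anova coef cor cor.test lm median p.adjust pbinom
#'   prcomp pt quantile rbinom rnorm rpois runif sd setNames t.test var var.test
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the previous RNG state so that
#' library calls never perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Splitmix-style integer mixing keeps per-stage streams decorrelated while the
#' result stays below 2^31 (R integers are 32-bit).
#'
#' @param seed master integer seed.
#' @param k stage index (integer >= 0) or stage name.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, k) {
  if (is.character(k)) k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
  x <- (as.double(seed) * 2654435761 + as.double(k) * 40503 + 12345) %% 2147483647
  as.integer(x)
}

# FNV-1a over serialized bytes; stand-in content hash (no digest pkg offline)
content_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  # skip the 14-byte serialization header (holds R version, not content)
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
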