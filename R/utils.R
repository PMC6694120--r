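#' @keywords internal
"_PACKAGE"

# 32-bit FNV-1a over a string; used for config hashes and for deriving
# per-operation seed substreams from one master seed.  Kept below 2^31 so it
# is always a valid R integer seed.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    # 16777619 * h mod 2^32 without overflow
    h <- (h * 16777619) %% 2^32
  }
  h
}

#' Derive a deterministic sub-seed from a master seed and a stream label
#'
#' Every randomized operation in the package draws its seed from the master
#' seed through a named substream, so adding genotypes or stages does not
#' perturb the random numbers used by others.
#'
#' @param seed master seed (integer).
#' @param stream character label of the substream.
#' @return an integer in [0, 2^31 - 1].
#' @export
sub_seed <- function(seed, stream) {
  as.integer(fnv1a32(paste0(format(seed, scientific = FALSE), "/", stream)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# fast OLS slope of y on x (single regressor with intercept)
ols_slope <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  dx <- x - mx
  sxx <- sum(dx * dx)
  if (sxx <= 0) return(NA_real_)
  sum(dx * (y - my)) / sxx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
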