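#' @useDynLib sdrdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft filter var sd median rnorm runif rpois quantile
#'   pnorm dnorm pchisq pf optim lm predict coef cor pt approx
#' @importFrom utils read.csv write.csv head
NULL

#' Derive a reproducible sub-seed from a top-level seed
#'
#' All randomness in the package flows from one integer seed. Each stage,
#' subject, condition and hemisphere gets its own stream by hashing the seed
#' together with a string tag (FNV-1a over the UTF-8 bytes, folded into the
#' positive 31-bit range R accepts in `set.seed()`).
#'
#' @param seed integer top-level seed.
#' @param ... character or numeric tags identifying the stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  tag <- paste(c(format(seed, scientific = FALSE), as.character(unlist(list(...)))),
               collapse = "\r")
  bytes <- utf8ToInt(tag)
  xor32 <- function(a, b) {
    # doubles can exceed .Machine$integer.max, so xor 16-bit halves
    bitwXor(a %% 65536, b %% 65536) + 65536 * bitwXor(a %/% 65536, b %/% 65536)
  }
  mul32 <- function(a, b) {
    # (a * b) mod 2^32 without exceeding 2^53: split a into 16-bit halves
    a0 <- a %% 65536; a1 <- a %/% 65536
    (a0 * b + ((a1 * b) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mul32(h, 16777619)
  }
  as.integer(h %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0)
    stopf("'%s' must be positive (got %g)", name, x)
  invisible(x)
}

#' Run an expression with a private RNG state
#'
#' Saves and restores `.Random.seed` so that library internals never disturb
#' the caller's stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
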