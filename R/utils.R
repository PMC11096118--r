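#' @importFrom rlang abort warn .data
#' @importFrom stats qt sd rnorm runif pbinom fft mvfft nextn dist median
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible child seed from a master seed and a purpose label.
# Keeps everything below 2^31 so it is a valid R integer seed.
derive_seed <- function(master, purpose) {
  stopifnot(is.numeric(master), length(master) == 1)
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(master) * 48271 + h * 16807) %% 2147483647L)
}

# Evaluate `expr` under a locally-set RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", name, lower, upper))
  }
  invisible(x)
}
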