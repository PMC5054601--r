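#' @importFrom stats rbinom rlnorm rmultinom rnorm runif sd setNames
#' @importFrom utils head read.table tail write.table packageVersion
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed, kept inside 32-bit
# integer range so they remain valid arguments to set.seed().
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 10007L * seq_len(n)) %% 2147483647L
}

stop_argument <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("dropmda_argument_error", "error", "condition")))
}

stop_parse <- function(msg) {
  stop(errorCondition(msg, class = c("dropmda_parse_error", "error", "condition")))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_argument(sprintf("`%s` must lie in [0, 1]", name))
  invisible(x)
}
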