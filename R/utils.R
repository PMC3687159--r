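# Internal helpers shared across modules.

#' Logistic sigmoid
#'
#' The hidden-layer activation used throughout: `1 / (1 + exp(-z))`.
#'
#' @param z Numeric vector or matrix.
#' @return Object of the same shape with values in (0, 1).
#' @export
logsig <- function(z) 1 / (1 + exp(-z))

# Deterministic 31-bit seed derived from an arbitrary key path, so that
# independent random streams (per cascade, per repetition, per shuffle) can be
# re-created in isolation. Polynomial string hash mod a prime < 2^31; all
# intermediates stay far below 2^53 so double arithmetic is exact.
derive_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)),
               collapse = "|")
  h <- 17
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# stopifnot() with a formatted message.
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
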