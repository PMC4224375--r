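# Internal helpers shared across modules.

#' Evaluate an expression with a temporary, fully specified RNG state
#'
#' Runs `code` after seeding the Mersenne-Twister generator (with the
#' "Rejection" sampling algorithm, so draws are reproducible across R
#' versions), then restores the caller's RNG state.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

#' Derive a reproducible sub-seed from a base seed and a key
#'
#' Experiments draw many independent subsamples (per repeat, per replicate,
#' per role).  Each draw gets its own seed derived deterministically from the
#' experiment's base seed and a string key, via a multiplicative-congruential
#' hash over the key's bytes.  The result is always in `[1, 2^31 - 2]`.
#'
#' @param base_seed integer base seed.
#' @param ... components (coerced to character) identifying the draw,
#'   e.g. repeat index, replicate label, role.
#' @return An integer seed.
#' @export
#' @examples
#' derive_seed(1L, "rep", 1, "M")
derive_seed <- function(base_seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1L)), collapse = "/")
  h <- as.double(as.integer(base_seed)) %% 2147483647
  if (h < 0) h <- h + 2147483647
  for (ch in utf8ToInt(key)) {
    # 69069 * 2^31 < 2^53: exact in double arithmetic
    h <- (h * 69069 + ch) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# Stop with a classed condition so callers can test error categories.
pc_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "poolctrl_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# round() in R rounds half to even, which is exactly the deterministic
# rounding rule used for subsample sizes; alias for readability.
round_half_even <- function(x) round(x)
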