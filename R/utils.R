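# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Stage-level generators (semantics, participants, responses) are seeded
#' independently so that re-running one stage alone reproduces its output.
#' The split uses a Lehmer step modulo the Mersenne prime 2^31 - 1, keeping
#' results inside R's integer range.
#'
#' @param seed integer master seed.
#' @param stream positive integer stream index.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  for (i in seq_len(stream)) s <- (s * 48271 + 11) %% m
  as.integer(max(1, s %% (m - 1)))
}

abort_validation <- function(msg, file = NULL, row = NULL) {
  loc <- c(
    if (!is.null(file)) sprintf("file '%s'", file),
    if (!is.null(row)) sprintf("row %s", paste(row, collapse = ", "))
  )
  if (length(loc)) msg <- sprintf("%s [%s]", msg, paste(loc, collapse = ", "))
  stop(structure(
    class = c("parosim_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_one_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
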