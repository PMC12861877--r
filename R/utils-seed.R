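#' Derive a stage-specific sub-seed from a run seed
#'
#' Every stochastic stage of the pipeline draws its own sub-seed from the
#' single run seed so that stages can be re-run in isolation and adding a
#' stage never perturbs the randomness of the others. The scheme is a simple
#' multiplicative hash of the run seed and a stage label, reduced modulo
#' 2^31 - 2 so the result is always a valid, strictly positive R integer.
#'
#' @param seed integer run seed.
#' @param label character stage label (e.g. `"simulate/GU"`).
#' @return a positive integer sub-seed, deterministic in `(seed, label)`.
#' @export
#' @examples
#' sub_seed(7L, "simulate/GU")
sub_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(seed) %% m)
  for (ch in utf8ToInt(label)) {
    # Horner update; operands stay < 2^53 so double arithmetic is exact
    h <- (h * 69069 + ch) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
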