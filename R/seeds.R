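#' Derive a child seed from a master seed
#'
#' Stochastic pipeline stages each consume their own seed so that any stage
#' can be re-run in isolation and reproduce its output. Child seeds are
#' derived deterministically from the master seed, a stage name and a
#' repetition index via a polynomial string hash reduced modulo 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param stage Character stage name.
#' @param rep Repetition index (default 0).
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "tuning")
#' derive_seed(1, "tuning", 3)
derive_seed <- function(master, stage, rep = 0) {
  stopifnot(length(master) == 1, length(stage) == 1, length(rep) == 1)
  key <- sprintf("%d/%s/%d", as.integer(master), stage, as.integer(rep))
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Run code under a local seed without touching the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
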