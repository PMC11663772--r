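#' Derive a child seed from a master seed
#'
#' Stage-level reproducibility: a master experiment seed is expanded into
#' independent child seeds through a counter-based integer hash, so each
#' pipeline stage (simulation, permutation replicate, bootstrap replicate, ...)
#' seeds its own RNG stream and replicate results do not depend on execution
#' order.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"perm"`.
#' @param index non-negative replicate counter within the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42L, "perm", 1)
child_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.double(master) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  h <- (h * 131 + (as.double(index) %% m)) %% m
  # multiplicative mix (Park-Miller constant), keep strictly inside [1, m-1]
  h <- (h * 48271) %% m
  as.integer(h + 1)
}
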