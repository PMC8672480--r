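#' Derive a named substream seed from a master seed
#'
#' Every stochastic stage of the pipeline (base means, variances,
#' individual means, eQTL assignment, DE factors, design, batch factors,
#' library sizes, counts, dropout) draws from its own substream derived
#' deterministically from the master seed and a stage name. Changing the
#' inputs of one stage therefore perturbs only that stage's draws.
#'
#' @param master integer master seed.
#' @param name character stage name.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% m
  as.integer((h * 48271 + (abs(master) %% m)) %% m)
}

with_substream <- function(master, name, expr) {
  set.seed(substream_seed(master, name))
  expr
}
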