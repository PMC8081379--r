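#' Derive a named sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' sub-streams (e.g. `"genome"`, `"planting"`, `"counts"`, `"nmf1"`), so a
#' stage can be re-run on its own and still reproduce the full-pipeline
#' result.  The derived seed is a deterministic 32-bit integer.
#'
#' @param seed Master seed (integer).
#' @param stream Stream name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' sub_seed(1, "genome")
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes) * 131)
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}
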