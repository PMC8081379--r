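#' Define a mutational signature for the synthetic generator
#'
#' A signature is a probability distribution over the 96 trinucleotide
#' substitution channels, plus the two nuisance parameters the generator
#' needs: the transcribed-strand bias applied to in-gene mutations and the
#' expected number of 1-bp indels planted per SNV.
#'
#' @param channel_probs Numeric vector of length 96, non-negative with a
#'   positive sum; normalized internally to sum to 1.  Order must follow
#'   [sbs_channels()].
#' @param ts_bias Fraction in `[0, 1]` of in-gene mutations whose pyrimidine
#'   lands on the transcribed (template) strand; `0.5` means no bias.
#' @param indel_rate Expected short indels planted per SNV (non-negative).
#' @param name Label for the signature.
#' @return An object of class `signature_spec`.
#' @export
#' @examples
#' sig <- signature_spec(rep(1 / 96, 96), name = "flat")
signature_spec <- function(channel_probs, ts_bias = 0.5, indel_rate = 0,
                           name = "signature") {
  if (length(channel_probs) != 96 || any(!is.finite(channel_probs)) ||
      any(channel_probs < 0) || sum(channel_probs) <= 0) {
    abort("`channel_probs` must be 96 non-negative finite values with a positive sum.")
  }
  if (!is.numeric(ts_bias) || ts_bias < 0 || ts_bias > 1) {
    abort("`ts_bias` must lie in [0, 1].")
  }
  if (!is.numeric(indel_rate) || indel_rate < 0) {
    abort("`indel_rate` must be non-negative.")
  }
  probs <- channel_probs / sum(channel_probs)
  structure(
    list(
      name = name,
      channel_probs = setNames(probs, channel_levels()),
      ts_bias = ts_bias,
      indel_rate = indel_rate
    ),
    class = "signature_spec"
  )
}

#' @export
print.signature_spec <- function(x, ...) {
  top <- sort(x$channel_probs, decreasing = TRUE)[1:5]
  cat("<signature_spec> ", x$name, "\n", sep = "")
  cat("  ts_bias = ", x$ts_bias, ", indel_rate = ", x$indel_rate, "\n", sep = "")
  cat("  top channels: ",
      paste0(names(top), " (", signif(top, 2), ")", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Built-in direct platinum signature
#'
#' The direct component of platinum mutagenesis: sharp `N[C>A]C` peaks
#' (intrastrand Pt-GG crosslinks read through the pyrimidine convention)
#' and `C[T>A]N` peaks (Pt-AG crosslinks).  All broad-spectrum mutagenesis
#' belongs to the background component, so the two built-in signatures have
#' distinct supports; this keeps the two-component decomposition
#' identifiable, which is what makes exposure splits between the direct and
#' indirect mechanisms meaningful.  The default transcribed-strand bias of
#' 0.8 reflects transcription-coupled repair of the purine-purine adducts.
#'
#' @param ts_bias,indel_rate See [signature_spec()].
#' @return A `signature_spec`.
#' @export
platinum_signature <- function(ts_bias = 0.8, indel_rate = 0.1) {
  ch <- sbs_channels()
  w <- rep(0, 96)
  ncc <- ch$class == "C>A" & ch$three == "C"       # N[C>A]C, 4 channels
  ctn <- ch$class == "T>A" & ch$five == "C"        # C[T>A]N, 4 channels
  w[ncc] <- 0.65 / sum(ncc)
  w[ctn] <- 0.35 / sum(ctn)
  signature_spec(w, ts_bias = ts_bias, indel_rate = indel_rate,
                 name = "platinum-direct")
}

#' Built-in background (spontaneous) signature
#'
#' The indirect, broad-spectrum component: a featureless SBS5/SBS40-like
#' distribution dominated by C>T and T>C with mass in every channel and no
#' strand bias.  It emulates the spontaneous mutagenesis seen in
#' mock-treated clones.
#'
#' @param ts_bias,indel_rate See [signature_spec()].
#' @return A `signature_spec`.
#' @export
background_signature <- function(ts_bias = 0.5, indel_rate = 0.1) {
  class_mass <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.30,
                  "T>A" = 0.09, "T>C" = 0.28, "T>G" = 0.15)
  ch <- sbs_channels()
  # mild, deterministic within-class tilt so the spectrum is smooth rather
  # than blocky: weight contexts by a fixed flank preference
  flank_w <- c(A = 1.2, C = 0.9, G = 0.9, T = 1.0)
  w <- class_mass[ch$class] * flank_w[ch$five] * flank_w[ch$three]
  w <- unname(w / sum(w))
  signature_spec(w, ts_bias = ts_bias, indel_rate = indel_rate,
                 name = "background")
}
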