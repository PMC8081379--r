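#' Re-estimate exposures for fixed signatures
#'
#' Kullback-Leibler refit of the exposure matrix with the signature matrix
#' held fixed (multiplicative updates on exposures only).  This is the
#' maximum-likelihood attribution of each sample's mutations to the given
#' signatures under the Poisson count model.
#'
#' @param V A `spectrum96` tibble or 96 x n count matrix.
#' @param signatures 96 x k column-normalized signature matrix.
#' @param max_iter,tol Iteration cap and relative divergence tolerance.
#' @return A k x n exposure matrix in mutation-count units.
#' @export
refit_exposures <- function(V, signatures, max_iter = 2000, tol = 1e-10) {
  if (is_tibble(V) || is.data.frame(V)) V <- spectrum_matrix(V)
  V <- as.matrix(V)
  S <- as.matrix(signatures)
  stopifnot(nrow(V) == nrow(S))
  eps <- 1e-12
  E <- matrix(colSums(V) / ncol(S), ncol(S), ncol(V),
              dimnames = list(colnames(S), colnames(V)))
  div <- Inf
  for (i in seq_len(max_iter)) {
    WH <- S %*% E
    E <- E * (t(S) %*% (V / pmax(WH, eps))) / pmax(colSums(S), eps)
    new_div <- kl_divergence(V, pmax(S %*% E, eps))
    if (is.finite(div) && abs(div - new_div) <= tol * max(abs(div), 1)) break
    div <- new_div
  }
  E
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

# Largest admixture coefficient c such that `s - c * other` stays a
# plausible signature: initialized by the `other`-weighted median of the
# channel ratios (the L1 regression slope), then refined by the mass ratio
# on the channels outside s's apparent own support, which aggregates counts
# and is far less noisy than per-channel ratios.
admixture_coef <- function(s, other, passes = 5) {
  c_est <- weighted_median(s / pmax(other, 1e-12), other)
  for (p in seq_len(passes)) {
    own <- s > 2 * c_est * other
    if (!any(!own) || !any(own)) break
    c_new <- sum(s[!own]) / sum(other[!own])
    if (abs(c_new - c_est) < 1e-8) {
      c_est <- c_new
      break
    }
    c_est <- c_new
  }
  c_est
}

#' Resolve the components of a rank-2 style NMF fit
#'
#' A non-negative factorization of mixed spectra is unique only up to a
#' non-negative recombination of its components: the maximum-likelihood fit
#' routinely returns a "platinum" component carrying a share of the broad
#' background (and vice versa), which biases exposure comparisons between
#' groups that differ in direct mutagen burden.  This function chooses the
#' scientifically meaningful representative of that solution family:
#'
#' 1. The background component is anchored.  If `background_samples` are
#'    given (mock-treated clones), their pooled normalized spectrum
#'    replaces the closest fitted component — mirroring the observation
#'    that the background component matches the spectrum of mock-treated
#'    cells.  Otherwise the broadest fitted component (smallest maximum
#'    channel load) is used as-is.
#' 2. Every other component is stripped of its background admixture: the
#'    admixture coefficient is estimated robustly (weighted-median
#'    initialization refined by an off-support mass ratio) and subtracted;
#'    channels left below `truncate_below` are zeroed, so the component
#'    keeps only its characteristic channels.
#' 3. Exposures are re-estimated against the resolved signatures with
#'    [refit_exposures()].
#'
#' @param fit A [nmf_fit()] result.
#' @param V The spectra the fit was computed on (tibble or matrix).
#' @param background_samples Optional character vector of sample names
#'   whose pooled spectrum anchors the background component.
#' @param truncate_below Channel-probability floor below which a resolved
#'   non-background component is considered noise (default `1/96`, the
#'   uniform level).  Set to 0 to disable truncation.
#' @param max_iter Refit iteration cap.
#' @return A `mut_nmf` object with resolved `signatures` and `exposures`,
#'   a `background_component` field and `method = "resolved"`.
#' @export
resolve_components <- function(fit, V, background_samples = NULL,
                               truncate_below = 1 / 96, max_iter = 2000) {
  stopifnot(inherits(fit, "mut_nmf"))
  if (is_tibble(V) || is.data.frame(V)) V <- spectrum_matrix(V)
  V <- as.matrix(V)
  S <- fit$signatures

  if (!is.null(background_samples)) {
    missing <- setdiff(background_samples, colnames(V))
    if (length(missing) > 0) {
      abort(paste0("background samples not in V: ",
                   paste(missing, collapse = ", ")))
    }
    sb <- rowSums(V[, background_samples, drop = FALSE])
    if (sum(sb) == 0) abort("background samples carry no mutations.")
    sb <- sb / sum(sb)
    b_idx <- which.max(apply(S, 2, function(s) cosine_similarity(s, sb)))
    S[, b_idx] <- sb
  } else {
    b_idx <- which.min(apply(S, 2, max))
    sb <- S[, b_idx]
  }

  for (j in setdiff(seq_len(ncol(S)), b_idx)) {
    s <- pmax(S[, j] - admixture_coef(S[, j], sb) * sb, 0)
    if (truncate_below > 0) s[s < truncate_below] <- 0
    if (sum(s) == 0) {
      abort("component collapsed to zero during resolution; it may not be distinguishable from the background.")
    }
    S[, j] <- s / sum(s)
  }
  E <- refit_exposures(V, S, max_iter = max_iter)
  out <- fit
  out$signatures <- S
  out$exposures <- E
  out$divergence <- kl_divergence(V, pmax(S %*% E, 1e-12))
  out$method <- "resolved"
  out$background_component <- colnames(S)[b_idx]
  out
}
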