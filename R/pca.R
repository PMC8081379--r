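#' Principal component analysis of normalized spectra
#'
#' Spectra are converted to relative channel frequencies (columns divided
#' by their sums) unless `normalize = FALSE`, channel-mean-centred across
#' samples and decomposed by singular value decomposition.  The sign of
#' each principal component is fixed by making its largest-magnitude
#' channel loading positive, so coordinates are reproducible.
#'
#' @param V A `spectrum96` tibble or a 96 x n matrix (channels x samples),
#'   n >= 2.
#' @param normalize Divide each sample's spectrum by its total first.
#' @return An object of class `spectra_pca` with `scores` (tibble, one row
#'   per sample), `explained` (variance fractions) and `rotation` (channel
#'   loadings).
#' @export
pca_spectra <- function(V, normalize = TRUE) {
  if (is_tibble(V) || is.data.frame(V)) V <- spectrum_matrix(V)
  V <- as.matrix(V)
  if (ncol(V) < 2) abort("PCA needs at least 2 samples.")
  if (normalize) {
    tot <- colSums(V)
    if (any(tot == 0)) abort("cannot normalize all-zero sample columns.")
    V <- sweep(V, 2, tot, "/")
  }
  pr <- prcomp(t(V), center = TRUE, scale. = FALSE)
  for (i in seq_len(ncol(pr$rotation))) {
    j <- which.max(abs(pr$rotation[, i]))
    if (pr$rotation[j, i] < 0) {
      pr$rotation[, i] <- -pr$rotation[, i]
      pr$x[, i] <- -pr$x[, i]
    }
  }
  total_var <- sum(pr$sdev^2)
  explained <- if (total_var > 0) pr$sdev^2 / total_var else
    rep(0, length(pr$sdev))
  scores <- as_tibble(pr$x, rownames = "sample")
  structure(
    list(scores = scores, explained = explained, rotation = pr$rotation,
         center = pr$center),
    class = "spectra_pca"
  )
}

#' @export
print.spectra_pca <- function(x, ...) {
  cat("<spectra_pca> ", nrow(x$scores), " samples; PC1 ",
      round(100 * x$explained[1], 1), "%, PC2 ",
      round(100 * (x$explained[2] %||% 0), 1), "% of variance\n", sep = "")
  invisible(x)
}

#' @rdname pca_spectra
#' @param x A `spectra_pca` object.
#' @param ... Unused.
#' @export
tidy.spectra_pca <- function(x, ...) x$scores

#' @rdname pca_spectra
#' @export
glance.spectra_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    pc1_var = x$explained[1],
    pc2_var = if (length(x$explained) >= 2) x$explained[2] else NA_real_
  )
}
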