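BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T only).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(
    strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
    function(s) paste(rev(s), collapse = ""),
    character(1)
  )
  unname(out)
}

# Frozen 96-channel order: substitution classes C>A, C>G, C>T, T>A, T>C, T>G
# (pyrimidine-centred), each expanded by 5' flank then 3' flank, both
# alphabetical.  This is the conventional single-base-substitution channel
# order used by signature catalogues ("A[C>A]A" ... "T[T>G]T").
.channel_table <- local({
  grid <- expand.grid(
    three = BASES, five = BASES, class = SUB_CLASSES,
    stringsAsFactors = FALSE
  )
  ref <- substr(grid$class, 1, 1)
  alt <- substr(grid$class, 3, 3)
  tibble::tibble(
    channel = paste0(grid$five, "[", grid$class, "]", grid$three),
    class   = grid$class,
    five    = grid$five,
    three   = grid$three,
    ref     = ref,
    alt     = alt,
    context = paste0(grid$five, ref, grid$three)
  )
})

#' The frozen 96-channel trinucleotide substitution table
#'
#' One row per pyrimidine-centred substitution channel, in the fixed order
#' used throughout the package and in serialized spectra: the six classes
#' `C>A, C>G, C>T, T>A, T>C, T>G`, each expanded by 5' then 3' flanking base
#' in alphabetical order (`A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`).
#'
#' @return A 96-row tibble with columns `channel`, `class`, `five`, `three`,
#'   `ref`, `alt` and `context` (the pyrimidine-strand trinucleotide).
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() .channel_table

channel_levels <- function() .channel_table$channel

#' Classify single-nucleotide variants into 96 trinucleotide channels
#'
#' Applies the pyrimidine-centred convention: when the reference base is a
#' purine the context and both alleles are reverse-complemented before
#' lookup, so every substitution maps to exactly one of the 96 channels.
#'
#' @param context Character vector of reference trinucleotides (the mutated
#'   base with its 5' and 3' neighbours, reference strand).
#' @param ref,alt Character vectors of reference and alternate bases
#'   (reference strand).
#' @return A factor with the 96 frozen channel levels.  Contexts containing
#'   non-ACGT characters (or `NA`) are unresolvable and yield `NA`.
#' @export
#' @examples
#' classify_snv("ACG", "C", "T")  # A[C>T]G
#' classify_snv("TGA", "G", "A")  # reverse complement -> T[C>T]A
classify_snv <- function(context, ref, alt) {
  n <- length(context)
  stopifnot(length(ref) == n, length(alt) == n)
  ok <- !is.na(context) & !is.na(ref) & !is.na(alt) &
    nchar(context) == 3 &
    !str_detect(context, "[^ACGT]") &
    ref %in% BASES & alt %in% BASES
  if (any(ok & substr(context, 2, 2) != ref)) {
    abort("`context` middle base must equal `ref` for resolvable contexts.")
  }
  if (any(ok & ref == alt)) {
    abort("`ref` and `alt` must differ.")
  }
  lab <- rep(NA_character_, n)
  if (any(ok)) {
    purine <- ref[ok] %in% c("A", "G")
    ctx <- ifelse(purine, revcomp(context[ok]), context[ok])
    r <- ifelse(purine, comp_base(ref[ok]), ref[ok])
    a <- ifelse(purine, comp_base(alt[ok]), alt[ok])
    lab[ok] <- paste0(substr(ctx, 1, 1), "[", r, ">", a, "]", substr(ctx, 3, 3))
  }
  factor(lab, levels = channel_levels())
}

#' Cosine similarity between non-negative vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return The cosine of the angle between `a` and `b`; 0 if either vector
#'   is all zero.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

cosine_matrix <- function(A, B) {
  out <- matrix(0, ncol(A), ncol(B), dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      out[i, j] <- cosine_similarity(A[, i], B[, j])
    }
  }
  out
}
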