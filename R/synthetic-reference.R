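#' Generate a synthetic reference genome with gene annotations
#'
#' Draws an i.i.d. base sequence with a given stationary GC content and
#' places non-overlapping gene intervals on random strands until roughly
#' `gene_fraction` of the genome is genic.  Intervals are 0-based
#' half-open, the convention used internally everywhere; coordinates become
#' 1-based only in serialized tables and VCF.
#'
#' @param length_bp Total genome length (>= 10000).
#' @param gene_fraction Target fraction of the genome covered by genes, in
#'   `[0, 1)`.
#' @param gc Stationary GC content, in `(0, 1)`.
#' @param seed Master seed (the `"genome"` sub-stream is used).
#' @param n_contigs Number of equally sized contigs.
#' @param gene_length_range Gene lengths are drawn uniformly from this range.
#' @return An object of class `ref_genome`: a list with `contigs` (named
#'   character vector of uppercase DNA) and `genes` (tibble with `contig`,
#'   `start`, `end`, `strand`, `gene_id`; 0-based half-open, genes never
#'   overlap).
#' @export
#' @examples
#' ref <- make_reference(20000, gene_fraction = 0.3, gc = 0.42, seed = 1)
make_reference <- function(length_bp, gene_fraction = 0.3, gc = 0.42,
                           seed = 1, n_contigs = 1,
                           gene_length_range = c(1000, 5000)) {
  if (length_bp < 10000) abort("`length_bp` must be at least 10000.")
  if (gc <= 0 || gc >= 1) abort("`gc` must lie strictly between 0 and 1.")
  if (gene_fraction < 0 || gene_fraction >= 1) {
    abort("`gene_fraction` must lie in [0, 1).")
  }
  contig_len <- floor(length_bp / n_contigs)
  if (gene_fraction > 0 && contig_len < min(gene_length_range)) {
    abort("contigs are too short to place a single gene.")
  }
  base_probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  withr::with_seed(sub_seed(seed, "genome"), {
    lens <- rep(contig_len, n_contigs)
    lens[n_contigs] <- length_bp - contig_len * (n_contigs - 1)
    names(lens) <- paste0("chr", seq_len(n_contigs))

    contigs <- vapply(lens, function(L) {
      paste(sample(BASES, L, replace = TRUE, prob = base_probs), collapse = "")
    }, character(1))

    genes <- list()
    if (gene_fraction > 0) {
      # alternate intergenic gaps and genes along each contig; the mean gap
      # is set so the expected genic fraction matches `gene_fraction`
      mean_gene <- mean(gene_length_range)
      mean_gap <- mean_gene * (1 - gene_fraction) / gene_fraction
      gid <- 0L
      for (cname in names(lens)) {
        p <- 0L
        L <- lens[[cname]]
        repeat {
          gap <- ceiling(stats::rexp(1, rate = 1 / mean_gap))
          glen <- round(runif(1, gene_length_range[1], gene_length_range[2]))
          start <- p + gap
          if (start + glen > L) break
          gid <- gid + 1L
          genes[[length(genes) + 1L]] <- tibble(
            contig = cname, start = as.integer(start),
            end = as.integer(start + glen),
            strand = sample(c("+", "-"), 1), gene_id = paste0("gene", gid)
          )
          p <- start + glen
        }
      }
    }
    genes <- if (length(genes) > 0) bind_rows(genes) else {
      tibble(contig = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character())
    }
    structure(list(contigs = contigs, genes = genes), class = "ref_genome")
  })
}

#' @export
print.ref_genome <- function(x, ...) {
  lens <- nchar(x$contigs)
  cat("<ref_genome> ", length(lens), " contig(s), ",
      format(sum(lens), big.mark = ","), " bp, ",
      nrow(x$genes), " genes (",
      round(100 * sum(x$genes$end - x$genes$start) / sum(lens), 1),
      "% genic)\n", sep = "")
  invisible(x)
}

#' Extract the reference trinucleotide context at a position
#'
#' @param ref A `ref_genome`.
#' @param contig,pos Character and integer vectors (1-based positions).
#' @return Character vector of trinucleotides; `NA` at contig edges.
#' @export
ref_context <- function(ref, contig, pos) {
  stopifnot(inherits(ref, "ref_genome"))
  lens <- nchar(ref$contigs)
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 2 & pos <= lens[contig] - 1
  if (any(ok)) {
    out[ok] <- vapply(which(ok), function(i) {
      substr(ref$contigs[[contig[i]]], pos[i] - 1, pos[i] + 1)
    }, character(1))
  }
  out
}

ref_base_at <- function(ref, contig, pos) {
  vapply(seq_along(pos), function(i) {
    substr(ref$contigs[[contig[i]]], pos[i], pos[i])
  }, character(1))
}

#' Index every genomic position by pyrimidine-centred trinucleotide context
#'
#' Internal workhorse for channel-conditional mutation placement and strand
#' annotation.  Each interior position is assigned one of the 32
#' pyrimidine-centred contexts and the strand (`"+"` or `"-"`) on which the
#' pyrimidine sits, plus the enclosing gene (if any) and its strand.
#'
#' @param ref A `ref_genome`.
#' @return A tibble with `contig`, `pos` (1-based), `ctx32` (0..31),
#'   `pyr_strand`, `in_gene`, `gene_strand`.
#' @keywords internal
context_index <- function(ref) {
  res <- lapply(names(ref$contigs), function(cname) {
    code <- match(strsplit(ref$contigs[[cname]], "", fixed = TRUE)[[1]], BASES)
    L <- length(code)
    if (L < 3) return(NULL)
    five <- code[1:(L - 2)]
    mid <- code[2:(L - 1)]
    three <- code[3:L]
    pyr <- mid == 2L | mid == 4L
    f <- ifelse(pyr, five, 5L - three)
    m <- ifelse(pyr, mid, 5L - mid)
    t3 <- ifelse(pyr, three, 5L - five)
    ctx32 <- ifelse(m == 2L, 0L, 16L) + (f - 1L) * 4L + (t3 - 1L)
    pos <- 2:(L - 1)

    g <- ref$genes[ref$genes$contig == cname, , drop = FALSE]
    in_gene <- rep(FALSE, length(pos))
    gene_strand <- rep(NA_character_, length(pos))
    if (nrow(g) > 0) {
      g <- g[order(g$start), , drop = FALSE]
      idx <- findInterval(pos - 1L, g$start)   # 0-based position vs starts
      hit <- idx >= 1L & (pos - 1L) < g$end[pmax(idx, 1L)]
      in_gene[hit] <- TRUE
      gene_strand[hit] <- g$strand[idx[hit]]
    }
    tibble(contig = cname, pos = pos, ctx32 = as.integer(ctx32),
           pyr_strand = ifelse(pyr, "+", "-"),
           in_gene = in_gene, gene_strand = gene_strand)
  })
  bind_rows(res)
}

# map each of the 96 channels to its 32-context id (same encoding as
# context_index: 0 for C-centred, 16 for T-centred, then 5' and 3' flanks)
channel_ctx32 <- function() {
  ch <- sbs_channels()
  mid2 <- ifelse(ch$ref == "C", 0L, 16L)
  mid2 + (match(ch$five, BASES) - 1L) * 4L + (match(ch$three, BASES) - 1L)
}
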