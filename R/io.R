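#' Read and write the pipeline's file formats
#'
#' All serialized tables are plain TSV.  Genomic intervals are 0-based
#' half-open internally and in BED; positions are 1-based in the counts
#' table, the truth table, the calls table and VCF.
#'
#' @name platmut-io
NULL

#' @describeIn platmut-io Write the reference as FASTA (and genes as BED if
#'   a `genes_path` is given).
#' @param ref A `ref_genome`.
#' @param path Output file path.
#' @param genes_path Optional BED output path for the gene annotation.
#' @export
write_reference_fasta <- function(ref, path, genes_path = NULL) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs), path)
  if (!is.null(genes_path)) write_genes_bed(ref$genes, genes_path)
  invisible(path)
}

#' @describeIn platmut-io Read a FASTA reference (optionally with a BED
#'   gene annotation) back into a `ref_genome`.
#' @export
read_reference_fasta <- function(path, genes_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  genes <- if (!is.null(genes_path)) read_genes_bed(genes_path) else {
    tibble(contig = character(), start = integer(), end = integer(),
           strand = character(), gene_id = character())
  }
  structure(list(contigs = contigs, genes = genes), class = "ref_genome")
}

#' @describeIn platmut-io Write genes as 6-column BED (0-based half-open,
#'   strand in column 6).
#' @param genes Gene tibble (`contig`, `start`, `end`, `strand`,
#'   `gene_id`).
#' @export
write_genes_bed <- function(genes, path) {
  bed <- tibble(
    chrom = genes$contig, start = genes$start, end = genes$end,
    name = genes$gene_id %||% paste0("gene", seq_len(nrow(genes))),
    score = 0L, strand = genes$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @describeIn platmut-io Read a 6-column BED gene annotation.
#' @export
read_genes_bed <- function(path) {
  bed <- readr::read_tsv(
    path, col_names = c("contig", "start", "end", "gene_id", "score", "strand"),
    col_types = "ciicic", progress = FALSE
  )
  if (any(is.na(bed$start)) || any(is.na(bed$end)) ||
      any(!bed$strand %in% c("+", "-"))) {
    bad <- which(is.na(bed$start) | is.na(bed$end) |
                   !bed$strand %in% c("+", "-"))[1]
    abort(paste0("malformed BED record at line ", bad, " of ", path))
  }
  bed |> select("contig", "start", "end", "strand", "gene_id")
}

#' @describeIn platmut-io Write a long `site_counts` table as the wide
#'   counts TSV (`contig`, `pos`, `ref_base`, then per sample `cov`, `A`,
#'   `C`, `G`, `T`, `ins_support`, `del_support`).
#' @param counts A `site_counts` tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  samples <- attr(counts, "samples") %||% unique(counts$sample)
  wide <- counts |>
    mutate(sample = factor(.data$sample, levels = samples)) |>
    arrange(.data$contig, .data$pos, .data$sample) |>
    pivot_wider(
      id_cols = c("contig", "pos", "ref_base"),
      names_from = "sample",
      values_from = c("cov", "A", "C", "G", "T", "ins_support", "del_support"),
      names_glue = "{sample}.{.value}"
    )
  # order columns sample-major
  cols <- c("contig", "pos", "ref_base",
            as.vector(t(outer(samples,
                              c("cov", "A", "C", "G", "T",
                                "ins_support", "del_support"),
                              paste, sep = "."))))
  readr::write_tsv(wide[, cols], path)
  invisible(path)
}

#' @describeIn platmut-io Read a wide counts TSV back to the long
#'   `site_counts` form.
#' @export
read_counts_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  needed <- c("contig", "pos", "ref_base")
  if (!all(needed %in% names(wide))) {
    abort(paste0("counts table ", path,
                 " lacks the contig/pos/ref_base columns."))
  }
  samples <- unique(sub("\\.[^.]+$", "", setdiff(names(wide), needed)))
  long <- wide |>
    pivot_longer(-all_of(needed),
                 names_to = c("sample", ".value"), names_sep = "\\.")
  long <- long |>
    mutate(sample = factor(.data$sample, levels = samples)) |>
    arrange(.data$contig, .data$pos, .data$sample) |>
    mutate(sample = as.character(.data$sample))
  class(long) <- c("site_counts", class(tibble()))
  attr(long, "samples") <- samples
  long
}

#' @describeIn platmut-io Write a planted-truth table as TSV (1-based
#'   positions).
#' @param truth A `planted_truth` tibble.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @describeIn platmut-io Read a planted-truth TSV.
#' @export
read_truth_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  class(out) <- c("planted_truth", class(tibble()))
  out
}

#' @describeIn platmut-io Write mutation calls as a flat TSV.
#' @param calls A `mutation_calls` tibble.
#' @export
write_calls_tsv <- function(calls, path) {
  readr::write_tsv(as_tibble(calls), path)
  invisible(path)
}

#' @describeIn platmut-io Read a calls TSV.
#' @export
read_calls_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  class(out) <- c("mutation_calls", class(tibble()))
  out
}

#' Write per-clone VCF 4.2 files
#'
#' One VCF per clone, with `SCORE` (the -log10 Fisher p quality score),
#' `VAF` and `TYPE` INFO fields.  Indel calls detected from the counts
#' table carry symbolic `<INS>`/`<DEL>` alternate alleles because the
#' counts format does not encode indel sequences.
#'
#' @param calls A `mutation_calls` tibble.
#' @param ref The `ref_genome` (for contig header lines).
#' @param dir Output directory; files are named `<sample>.vcf`.
#' @return Invisibly, the paths written.
#' @export
write_vcf <- function(calls, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contig_lines <- paste0("##contig=<ID=", names(ref$contigs),
                         ",length=", nchar(ref$contigs), ">")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=platmut",
    contig_lines,
    "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"-log10 Fisher quality score\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNV, INS or DEL\">",
    "##ALT=<ID=INS,Description=\"Short insertion of undetermined sequence\">",
    "##ALT=<ID=DEL,Description=\"Short deletion of undetermined sequence\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  paths <- character(0)
  for (s in unique(calls$sample)) {
    cs <- calls |>
      filter(.data$sample == s) |>
      arrange(.data$contig, .data$pos)
    body <- sprintf(
      "%s\t%d\t.\t%s\t%s\t%.4f\tPASS\tSCORE=%.6g;VAF=%.6g;TYPE=%s",
      cs$contig, cs$pos, cs$ref, cs$alt, cs$score, cs$score, cs$vaf, cs$type
    )
    p <- file.path(dir, paste0(s, ".vcf"))
    writeLines(c(header, body), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a per-clone VCF back into a calls tibble
#'
#' @param path A VCF written by [write_vcf()].
#' @param sample Sample id to assign (defaults to the file name).
#' @return A `mutation_calls` tibble (without contexts).
#' @export
read_vcf_calls <- function(path, sample = NULL) {
  sample <- sample %||% sub("\\.vcf$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble(sample = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  type = character(), score = double(), vaf = double())
  } else {
    info_field <- function(info, key) {
      m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
      sub(paste0(key, "="), "", m)
    }
    out <- tibble(
      sample = sample,
      contig = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      type = info_field(fix$INFO, "TYPE"),
      score = as.numeric(info_field(fix$INFO, "SCORE")),
      vaf = as.numeric(info_field(fix$INFO, "VAF"))
    )
  }
  class(out) <- c("mutation_calls", class(tibble()))
  out
}

#' @describeIn platmut-io Write spectra as TSV: a `channel` column with the
#'   96 frozen labels plus one column per sample/group.
#' @param spectra A `spectrum96` tibble.
#' @export
write_spectrum_tsv <- function(spectra, path) {
  m <- spectrum_matrix(spectra)
  readr::write_tsv(as_tibble(m, rownames = "channel"), path)
  invisible(path)
}

#' @describeIn platmut-io Read a spectrum TSV; channel labels must match
#'   the frozen order exactly (the first offending label is reported).
#' @export
read_spectrum_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"channel" %in% names(wide)) abort("spectrum TSV lacks a `channel` column.")
  check_channel_labels(wide$channel, path)
  out <- wide |>
    pivot_longer(-"channel", names_to = "sample", values_to = "count") |>
    mutate(channel = factor(.data$channel, levels = channel_levels())) |>
    arrange(.data$sample, .data$channel)
  class(out) <- c("spectrum96", class(tibble()))
  out
}

check_channel_labels <- function(labels, path = "input") {
  if (length(labels) != 96) {
    abort(paste0(path, ": expected 96 channel rows, found ", length(labels)))
  }
  mism <- which(labels != channel_levels())
  if (length(mism) > 0) {
    abort(paste0(path, ": channel label \"", labels[mism[1]],
                 "\" does not match the expected \"",
                 channel_levels()[mism[1]], "\""))
  }
  invisible(TRUE)
}

#' @describeIn platmut-io Write fitted signatures (96 x k) as TSV.
#' @param fit A `mut_nmf` object or signature matrix.
#' @export
write_signatures_tsv <- function(fit, path) {
  S <- if (inherits(fit, "mut_nmf")) fit$signatures else as.matrix(fit)
  readr::write_tsv(as_tibble(S, rownames = "channel"), path)
  invisible(path)
}

#' @describeIn platmut-io Read a 96-row signature TSV (e.g. an external
#'   reference catalogue with `channel` plus one column per signature).
#' @export
read_signatures_tsv <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!"channel" %in% names(wide)) abort("signature TSV lacks a `channel` column.")
  check_channel_labels(wide$channel, path)
  wide
}

#' @describeIn platmut-io Write exposures (k x samples) as TSV.
#' @export
write_exposures_tsv <- function(fit, path) {
  E <- if (inherits(fit, "mut_nmf")) fit$exposures else as.matrix(fit)
  readr::write_tsv(as_tibble(E, rownames = "component"), path)
  invisible(path)
}
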