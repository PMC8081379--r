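#' Build 96-channel trinucleotide spectra from mutation calls
#'
#' Tallies context-resolvable SNVs into the frozen 96-channel order, per
#' sample or per group.  With `mode = "average"` the per-sample spectra of
#' each group are averaged channel-wise (samples with no calls contribute
#' zero spectra), matching how per-treatment spectra are reported.
#'
#' @param calls A `mutation_calls` tibble (or any tibble with `sample`,
#'   `ref`, `alt`, `type`, `context` columns).
#' @param groups Optional tibble mapping `sample` to `group`; when given,
#'   spectra are aggregated by group.
#' @param mode `"sum"` (default) or `"average"` (only meaningful with
#'   `groups`).
#' @param exclude_dbs Drop SNVs that form adjacent doublet substitutions
#'   (see [classify_dbs()]) before tallying.  Default `FALSE`.
#' @return A tibble of class `spectrum96` with columns `sample` (or
#'   `group`), `channel` (factor with the 96 frozen levels) and `count`;
#'   every channel is present for every unit.  The number of SNVs dropped
#'   for unresolvable context is attached as attribute `dropped`.
#' @export
build_spectrum <- function(calls, groups = NULL,
                           mode = c("sum", "average"),
                           exclude_dbs = FALSE) {
  mode <- match.arg(mode)
  snvs <- calls |> filter(.data$type == "SNV")
  if (exclude_dbs && nrow(snvs) > 0) {
    dbs <- classify_dbs(calls)
    if (nrow(dbs) > 0) {
      in_dbs <- bind_rows(
        dbs |> select("sample", "contig", pos = "pos1"),
        dbs |> select("sample", "contig", pos = "pos2")
      )
      snvs <- snvs |> anti_join(in_dbs, by = c("sample", "contig", "pos"))
    }
  }
  snvs <- snvs |> mutate(channel = classify_snv(.data$context, .data$ref, .data$alt))
  dropped <- sum(is.na(snvs$channel))
  snvs <- snvs |> filter(!is.na(.data$channel))

  if (!is.null(groups)) {
    groups <- as_tibble(groups)
    stopifnot(all(c("sample", "group") %in% names(groups)))
    if (nrow(groups) == 0) abort("`groups` maps no samples.")
    unit_samples <- groups
    snvs <- snvs |> inner_join(groups, by = "sample")
    per_sample <- snvs |>
      count(.data$group, .data$sample, .data$channel,
            .drop = FALSE, name = "count") |>
      # complete() over all mapped samples so empty call sets count as zeros
      right_join(crossing(unit_samples,
                          channel = factor(channel_levels(),
                                           levels = channel_levels())),
                 by = c("group", "sample", "channel")) |>
      mutate(count = replace_na(.data$count, 0L))
    out <- per_sample |>
      group_by(.data$group, .data$channel) |>
      summarise(count = if (mode == "sum") sum(.data$count)
                else mean(.data$count), .groups = "drop")
  } else {
    if (nrow(snvs) == 0 && nrow(calls) == 0) {
      abort("no calls to tally; supply at least one sample.")
    }
    all_samples <- unique(calls$sample)
    out <- snvs |>
      count(.data$sample, .data$channel, .drop = FALSE, name = "count") |>
      right_join(crossing(sample = all_samples,
                          channel = factor(channel_levels(),
                                           levels = channel_levels())),
                 by = c("sample", "channel")) |>
      mutate(count = replace_na(.data$count, 0L)) |>
      arrange(.data$sample, .data$channel)
  }
  out <- out |> mutate(channel = factor(.data$channel, levels = channel_levels()))
  class(out) <- c("spectrum96", class(tibble()))
  attr(out, "mode") <- mode
  attr(out, "dropped") <- dropped
  out
}

#' Convert a spectrum tibble to a 96 x n matrix
#'
#' @param spectra A `spectrum96` tibble (long form).
#' @return A numeric matrix with the 96 channels as rows (frozen order) and
#'   one column per sample/group.
#' @export
spectrum_matrix <- function(spectra) {
  unit <- if ("sample" %in% names(spectra)) "sample" else "group"
  wide <- spectra |>
    mutate(channel = factor(.data$channel, levels = channel_levels())) |>
    arrange(.data$channel) |>
    pivot_wider(id_cols = "channel", names_from = all_of(unit),
                values_from = "count")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$channel)
  m
}

#' Identify doublet base substitutions among SNV calls
#'
#' Adjacent same-sample SNVs (genomic distance 1) are merged into doublet
#' substitutions and classified with the canonical strand normalization:
#' the reference dinucleotide is reverse-complemented into the canonical
#' set \{AC, AT, CC, CG, CT, GC, TA, TC, TG, TT\}; for palindromic
#' reference dinucleotides the orientation with the lexicographically
#' smaller alternate dinucleotide is reported.  Runs of three or more
#' consecutive SNVs are multi-nucleotide events, excluded from the doublet
#' classes and counted in the `mnv_excluded` attribute.
#'
#' @param calls A `mutation_calls` tibble.
#' @return A tibble with one row per doublet: `sample`, `contig`, `pos1`,
#'   `pos2`, `ref`, `alt`, `dbs` (e.g. `"CC>AA"`).
#' @export
classify_dbs <- function(calls) {
  canonical <- c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
  snvs <- calls |>
    filter(.data$type == "SNV") |>
    arrange(.data$sample, .data$contig, .data$pos)
  empty <- tibble(sample = character(), contig = character(),
                  pos1 = integer(), pos2 = integer(), ref = character(),
                  alt = character(), dbs = character())
  if (nrow(snvs) < 2) {
    attr(empty, "mnv_excluded") <- 0L
    return(empty)
  }
  snvs <- snvs |>
    group_by(.data$sample, .data$contig) |>
    mutate(
      gap_prev = .data$pos - lag(.data$pos, default = -10L),
      gap_next = lead(.data$pos, default = 10L^9) - .data$pos
    ) |>
    ungroup() |>
    mutate(run = .data$gap_prev == 1L | .data$gap_next == 1L)

  adj <- snvs |> filter(.data$run)
  if (nrow(adj) == 0) {
    attr(empty, "mnv_excluded") <- 0L
    return(empty)
  }
  # label maximal runs of consecutive positions
  runs <- adj |>
    group_by(.data$sample, .data$contig) |>
    mutate(run_id = cumsum(.data$gap_prev != 1L)) |>
    group_by(.data$sample, .data$contig, .data$run_id) |>
    summarise(
      len = n(), pos1 = .data$pos[1], pos2 = .data$pos[n()],
      ref = paste(.data$ref, collapse = ""),
      alt = paste(.data$alt, collapse = ""),
      .groups = "drop"
    )
  mnv <- sum(runs$len >= 3)
  pairs <- runs |> filter(.data$len == 2)
  if (nrow(pairs) == 0) {
    attr(empty, "mnv_excluded") <- mnv
    return(empty)
  }
  ref2 <- pairs$ref
  alt2 <- pairs$alt
  rc_ref <- revcomp(ref2)
  rc_alt <- revcomp(alt2)
  flip <- !(ref2 %in% canonical) |
    (ref2 == rc_ref & rc_alt < alt2)
  ref_out <- ifelse(flip, rc_ref, ref2)
  alt_out <- ifelse(flip, rc_alt, alt2)
  out <- pairs |>
    transmute(sample = .data$sample, contig = .data$contig,
              pos1 = .data$pos1, pos2 = .data$pos2,
              ref = ref_out, alt = alt_out,
              dbs = paste0(ref_out, ">", alt_out))
  attr(out, "mnv_excluded") <- mnv
  out
}

#' Classify short indels by length and homopolymer context
#'
#' A simplified two-axis scheme: event length bucketed as 1, 2-4 or 5+
#' bases, and the homopolymer run length of the repeated base at the locus
#' bucketed as 0-1, 2-4 or 5+.  The run is counted on the reference around
#' the event (for deletions, the maximal run containing the deleted base;
#' for insertions, the run of the inserted base adjacent to the insertion
#' point), which makes the class invariant under reverse-complementing the
#' locus.
#'
#' @param calls A tibble of indel calls with anchored `ref`/`alt` alleles
#'   (e.g. a `planted_truth` or calls read back from VCF; symbolic alleles
#'   cannot be classified).
#' @param ref The `ref_genome`.
#' @return The input rows with `indel_len`, `len_bucket`, `homopolymer_run`
#'   and `run_bucket` columns added.
#' @export
classify_indel <- function(calls, ref) {
  ind <- calls |> filter(.data$type %in% c("INS", "DEL"))
  if (nrow(ind) == 0) {
    return(ind |> mutate(indel_len = integer(), len_bucket = character(),
                         homopolymer_run = integer(),
                         run_bucket = character()))
  }
  if (any(grepl("[<>]", ind$alt))) {
    abort("symbolic indel alleles cannot be classified; explicit alleles are required.")
  }
  len <- abs(nchar(ind$alt) - nchar(ind$ref))
  run <- vapply(seq_len(nrow(ind)), function(i) {
    seqs <- ref$contigs[[ind$contig[i]]]
    L <- nchar(seqs)
    if (ind$type[i] == "DEL") {
      base <- substr(ind$ref[i], 2, 2)
      at <- ind$pos[i] + 1L       # first deleted base
      left <- at
      while (left > 1 && substr(seqs, left - 1, left - 1) == base) left <- left - 1L
      right <- at
      while (right < L && substr(seqs, right + 1, right + 1) == base) right <- right + 1L
      right - left + 1L
    } else {
      base <- substr(ind$alt[i], 2, 2)  # first inserted base
      at <- ind$pos[i]                  # anchor; insertion between at, at+1
      r <- 0L
      j <- at
      while (j >= 1 && substr(seqs, j, j) == base) { r <- r + 1L; j <- j - 1L }
      j <- at + 1L
      while (j <= L && substr(seqs, j, j) == base) { r <- r + 1L; j <- j + 1L }
      r
    }
  }, integer(1))
  ind |>
    mutate(
      indel_len = len,
      len_bucket = as.character(cut(len, c(0, 1, 4, Inf),
                                    labels = c("1", "2-4", "5+"))),
      homopolymer_run = run,
      run_bucket = as.character(cut(run, c(-1, 1, 4, Inf),
                                    labels = c("0-1", "2-4", "5+")))
    )
}

#' Transcriptional strand bias of in-gene SNVs
#'
#' Each SNV falling inside an annotated gene is assigned to the transcribed
#' or untranscribed strand by comparing its pyrimidine strand (the strand
#' carrying the pyrimidine of the mutated pair) with the gene's strand: the
#' pyrimidine sits on the transcribed (template) strand when the two
#' differ.  Intergenic SNVs are excluded; SNVs covered by genes on both
#' strands are excluded and counted in the `ambiguous` attribute.  Each
#' substitution class is tested against symmetry with a two-sided exact
#' binomial test.
#'
#' @param calls A `mutation_calls` tibble with contexts.
#' @param genes Gene annotation tibble (`contig`, `start`, `end`, `strand`;
#'   0-based half-open), e.g. `ref$genes`.
#' @param per_channel Also stratify by the 96 channels instead of the six
#'   classes.
#' @return A tibble with `class` (or `channel`), `transcribed`,
#'   `untranscribed`, `ratio` and `p_value`.
#' @export
strand_bias <- function(calls, genes, per_channel = FALSE) {
  snvs <- calls |>
    filter(.data$type == "SNV") |>
    mutate(channel = classify_snv(.data$context, .data$ref, .data$alt)) |>
    filter(!is.na(.data$channel)) |>
    mutate(pyr_strand = ifelse(.data$ref %in% c("C", "T"), "+", "-"))

  strand_of <- function(contig, pos, want_strand) {
    g <- genes |> filter(.data$strand == want_strand)
    out <- rep(FALSE, length(pos))
    for (cn in unique(contig)) {
      gg <- g |> filter(.data$contig == cn) |> arrange(.data$start)
      if (nrow(gg) == 0) next
      sel <- contig == cn
      idx <- findInterval(pos[sel] - 1L, gg$start)
      out[sel] <- idx >= 1L & (pos[sel] - 1L) < gg$end[pmax(idx, 1L)]
    }
    out
  }
  in_plus <- strand_of(snvs$contig, snvs$pos, "+")
  in_minus <- strand_of(snvs$contig, snvs$pos, "-")
  ambiguous <- in_plus & in_minus
  snvs <- snvs |>
    mutate(gene_strand = case_when(ambiguous ~ NA_character_,
                                   in_plus ~ "+", in_minus ~ "-",
                                   TRUE ~ NA_character_)) |>
    filter(!is.na(.data$gene_strand)) |>
    mutate(ts = .data$pyr_strand != .data$gene_strand)

  key <- if (per_channel) "channel" else NULL
  snvs <- snvs |> mutate(class_ = substr(as.character(.data$channel), 3, 5))
  grp_cols <- c("class_", key)
  if (nrow(snvs) == 0) {
    out <- tibble(class = character(), transcribed = integer(),
                  untranscribed = integer(), ratio = double(),
                  p_value = double())
    attr(out, "ambiguous") <- sum(ambiguous)
    return(out)
  }
  out <- snvs |>
    group_by(across(all_of(grp_cols))) |>
    summarise(transcribed = sum(.data$ts),
              untranscribed = sum(!.data$ts), .groups = "drop") |>
    rowwise() |>
    mutate(
      ratio = ifelse(.data$untranscribed > 0,
                     .data$transcribed / .data$untranscribed, Inf),
      p_value = binom.test(.data$transcribed,
                           .data$transcribed + .data$untranscribed,
                           0.5)$p.value
    ) |>
    ungroup() |>
    rename(class = "class_")
  attr(out, "ambiguous") <- sum(ambiguous)
  out
}

#' Normalize a mutation burden to a per-Gb per-cell-cycle rate
#'
#' `rate = mutations / (genome_gb * duration_days * 24 / cycle_hours)`.
#' The genome size is an explicit argument (haploid reference scale, e.g.
#' 3.0 Gb for a human-like genome) so either the haploid or the diploid
#' convention can be chosen by the caller.
#'
#' @param mutations Mutation count (non-negative).
#' @param duration_days Duration of the experiment in days (> 0).
#' @param cycle_hours Cell cycle time in hours (> 0).
#' @param genome_gb Genome size in gigabases (> 0).
#' @return A one-row tibble with the inputs, the implied number of cell
#'   cycles and `rate_per_gb_per_cycle`.
#' @export
#' @examples
#' mutation_rate(169, 50, 16, 3.0)  # ~0.75 per Gb per cell cycle
mutation_rate <- function(mutations, duration_days, cycle_hours, genome_gb) {
  if (any(mutations < 0)) abort("`mutations` must be non-negative.")
  if (any(duration_days <= 0) || any(cycle_hours <= 0) || any(genome_gb <= 0)) {
    abort("`duration_days`, `cycle_hours` and `genome_gb` must be positive.")
  }
  cycles <- duration_days * 24 / cycle_hours
  tibble(
    mutations = mutations, duration_days = duration_days,
    cycle_hours = cycle_hours, genome_gb = genome_gb, cycles = cycles,
    rate_per_gb_per_cycle = mutations / (genome_gb * cycles)
  )
}
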