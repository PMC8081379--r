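#' Detect candidate unique mutations across isogenic samples
#'
#' A site yields a candidate if and only if exactly one sample shows the
#' variant (alternate-allele frequency at least `min_vaf` with coverage at
#' least `min_cov`) while every other sample looks clean (reference-allele
#' frequency at least `min_other_ref_freq` with coverage at least
#' `min_cov`).  Variants shared by two or more samples are by construction
#' not unique and are dropped.  SNV, insertion and deletion candidates are
#' detected independently at each site; sites where any sample has zero
#' coverage are skipped (their number is recorded in the `skipped_sites`
#' attribute).
#'
#' For each candidate the comparison sample needed by [score_candidates()]
#' is identified: among the non-mutated samples, the one with the lowest
#' reference-allele frequency (ties broken by sample name).
#'
#' @param counts A `site_counts` tibble from [emit_counts()] or
#'   [read_counts_tsv()].
#' @param min_vaf Minimum alternate-allele frequency in the mutated sample.
#' @param min_other_ref_freq Minimum reference-allele frequency in every
#'   other sample.
#' @param min_cov Minimum coverage in every sample.
#' @return A tibble with one row per candidate: `contig`, `pos`, `sample`,
#'   `type`, `ref_base`, `alt`, `cov`, `alt_count`, `ref_count`, `vaf`,
#'   `other_sample`, `other_alt`, `other_ref`, `other_zero_cov`.
#' @export
detect_candidates <- function(counts, min_vaf = 0.2,
                              min_other_ref_freq = 0.93, min_cov = 7) {
  stopifnot(all(c("contig", "pos", "ref_base", "sample", "cov",
                  "A", "C", "G", "T", "ins_support", "del_support")
                %in% names(counts)))

  x <- as_tibble(counts)
  bm <- as.matrix(x[, BASES])
  n <- nrow(x)
  ref_code <- match(x$ref_base, BASES)
  ref_n <- bm[cbind(seq_len(n), ref_code)]
  alt_m <- bm
  alt_m[cbind(seq_len(n), ref_code)] <- -1L
  top_alt_code <- max.col(alt_m, ties.method = "first")
  alt_n <- alt_m[cbind(seq_len(n), top_alt_code)]
  alt_n[alt_n < 0] <- 0L

  x <- x |>
    mutate(
      ref_n = ref_n,
      alt_n = alt_n,
      alt_base = BASES[top_alt_code],
      ref_freq = ifelse(.data$cov > 0, ref_n / .data$cov, 0),
      alt_freq = ifelse(.data$cov > 0, alt_n / .data$cov, 0),
      ins_freq = ifelse(.data$cov > 0, .data$ins_support / .data$cov, 0),
      del_freq = ifelse(.data$cov > 0, .data$del_support / .data$cov, 0)
    )

  site_ok <- x |>
    group_by(.data$contig, .data$pos) |>
    summarise(any_zero = any(.data$cov == 0), .groups = "drop")
  n_skipped <- sum(site_ok$any_zero)
  x <- x |>
    inner_join(filter(site_ok, !.data$any_zero),
               by = c("contig", "pos")) |>
    select(-"any_zero")

  candidates_for <- function(x, freq_col, support_col, clean_freq_expr,
                             type_label) {
    y <- x |>
      mutate(
        mut_ok = .data[[freq_col]] >= min_vaf & .data$cov >= min_cov,
        clean_ok = {{ clean_freq_expr }} >= min_other_ref_freq &
          .data$cov >= min_cov
      )
    sites <- y |>
      group_by(.data$contig, .data$pos) |>
      summarise(
        n_mut = sum(.data$mut_ok),
        n_clean_others = sum(.data$clean_ok & !.data$mut_ok),
        n_samples = n(),
        .groups = "drop"
      ) |>
      filter(.data$n_mut == 1, .data$n_clean_others == .data$n_samples - 1)
    if (nrow(sites) == 0) return(NULL)
    hits <- y |>
      semi_join(sites, by = c("contig", "pos"))
    mut <- hits |> filter(.data$mut_ok)
    others <- hits |>
      anti_join(select(mut, "contig", "pos", "sample"),
                by = c("contig", "pos", "sample"))
    if (type_label == "SNV") {
      # the comparison sample's counts are allele-specific: its count of the
      # candidate's alternate base vs its reference-base count
      others <- others |>
        left_join(select(mut, "contig", "pos", cand_alt = "alt_base"),
                  by = c("contig", "pos")) |>
        mutate(
          o_alt = as.matrix(pick("A", "C", "G", "T"))[
            cbind(row_number(), match(.data$cand_alt, BASES))],
          o_ref = .data$ref_n,
          o_freq = .data$ref_freq
        )
      mut <- mut |>
        mutate(alt = .data$alt_base, alt_count = .data$alt_n,
               ref_count = .data$ref_n, vaf = .data$alt_freq)
    } else {
      others <- others |>
        mutate(
          o_alt = .data[[support_col]],
          o_ref = .data$cov - .data[[support_col]],
          o_freq = (.data$cov - .data[[support_col]]) / .data$cov
        )
      mut <- mut |>
        mutate(alt = paste0("<", type_label, ">"),
               alt_count = .data[[support_col]],
               ref_count = .data$cov - .data[[support_col]],
               vaf = .data[[freq_col]])
    }
    comparison <- others |>
      arrange(.data$contig, .data$pos, .data$o_freq, .data$sample) |>
      group_by(.data$contig, .data$pos) |>
      slice(1) |>
      ungroup() |>
      select("contig", "pos", other_sample = "sample",
             other_alt = "o_alt", other_ref = "o_ref", other_cov = "cov")
    mut |>
      transmute(
        contig = .data$contig, pos = .data$pos, sample = .data$sample,
        type = type_label, ref_base = .data$ref_base, alt = .data$alt,
        cov = .data$cov, alt_count = .data$alt_count,
        ref_count = .data$ref_count, vaf = .data$vaf
      ) |>
      left_join(comparison, by = c("contig", "pos")) |>
      mutate(other_zero_cov = .data$other_cov == 0) |>
      select(-"other_cov")
  }

  out <- bind_rows(
    candidates_for(x, "alt_freq", NULL, .data$ref_freq, "SNV"),
    candidates_for(x, "ins_freq", "ins_support",
                   (.data$cov - .data$ins_support) / .data$cov, "INS"),
    candidates_for(x, "del_freq", "del_support",
                   (.data$cov - .data$del_support) / .data$cov, "DEL")
  )
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(contig = character(), pos = integer(), sample = character(),
                  type = character(), ref_base = character(),
                  alt = character(), cov = integer(), alt_count = integer(),
                  ref_count = integer(), vaf = double(),
                  other_sample = character(), other_alt = integer(),
                  other_ref = integer(), other_zero_cov = logical())
  }
  out <- arrange(out, .data$sample, .data$contig, .data$pos, .data$type)
  attr(out, "skipped_sites") <- n_skipped
  out
}

#' Score candidates with a one-sided Fisher exact test
#'
#' The quality score of a candidate is computed from the mutated sample and
#' the one other sample with the lowest reference-allele frequency: the
#' one-sided Fisher exact p-value that both samples' (alt, ref) read counts
#' come from the same allele fraction, against the alternative that the
#' mutated sample's alternate fraction is higher.  The score is
#' `-log10(p)`, with `p` clamped below at `1e-300`; a comparison sample
#' with zero coverage is uninformative and yields score 0 (flagged).
#'
#' @param candidates Output of [detect_candidates()].
#' @return The same tibble with `score` and `score_flagged` columns added.
#' @export
score_candidates <- function(candidates) {
  stopifnot(all(c("alt_count", "ref_count", "other_alt", "other_ref")
                %in% names(candidates)))
  a <- candidates$alt_count
  r <- candidates$ref_count
  oa <- candidates$other_alt
  orf <- candidates$other_ref
  # one-sided hypergeometric tail P(X >= a) for the 2x2 table
  # [a r; oa orf] with fixed margins
  p <- phyper(a - 1, a + oa, r + orf, a + r, lower.tail = FALSE)
  score <- -log10(pmax(p, 1e-300))
  zero <- !is.na(candidates$other_zero_cov) & candidates$other_zero_cov
  score[zero] <- 0
  candidates |>
    mutate(score = score, score_flagged = zero)
}

#' Calibrate score thresholds on control clones
#'
#' Reproduces the false-positive calibration rule: the SNV threshold is the
#' smallest score `T` (inclusive, i.e. a call survives iff `score >= T`)
#' such that every control clone retains at most `snv_limit` SNV calls;
#' insertions and deletions are calibrated the same way against their own
#' limits.  The sweep considers 0 and every observed score; if even the
#' largest observed score leaves a clone over its limit, the threshold is
#' set just above the largest score.
#'
#' @param control_calls Scored candidates ([score_candidates()]) from a run
#'   that includes the control clones.  Calls in non-control samples are
#'   ignored.
#' @param control_samples Character vector of control clone ids (must be
#'   non-empty; clones with no calls still count against the sweep).
#' @param snv_limit,ins_limit,del_limit Maximum false-positive calls
#'   tolerated per control clone and type (defaults 5, 1, 1).
#' @return An object of class `fp_calibration`: thresholds per type plus
#'   the per-clone surviving false-positive counts at those thresholds.
#' @export
calibrate_threshold <- function(control_calls, control_samples,
                                snv_limit = 5, ins_limit = 1, del_limit = 1) {
  if (missing(control_samples) || length(control_samples) == 0) {
    abort("`control_samples` must name at least one control clone.")
  }
  calls <- control_calls |>
    filter(.data$sample %in% control_samples)
  limits <- c(SNV = snv_limit, INS = ins_limit, DEL = del_limit)

  thr_one <- function(scores_by_clone, limit) {
    all_scores <- sort(unique(unlist(scores_by_clone, use.names = FALSE)))
    cands <- c(0, all_scores)
    for (T in cands) {
      counts <- vapply(control_samples, function(s) {
        sum(scores_by_clone[[s]] >= T)
      }, numeric(1))
      if (all(counts <= limit)) return(T)
    }
    max(all_scores) * (1 + 1e-9) + 1e-12
  }

  thresholds <- vapply(names(limits), function(tp) {
    sc <- calls |> filter(.data$type == tp)
    by_clone <- lapply(setNames(control_samples, control_samples),
                       function(s) sc$score[sc$sample == s])
    thr_one(by_clone, limits[[tp]])
  }, numeric(1))

  fp_counts <- crossing(sample = control_samples, type = names(limits)) |>
    left_join(
      calls |>
        filter(.data$score >= thresholds[.data$type]) |>
        count(.data$sample, .data$type),
      by = c("sample", "type")
    ) |>
    mutate(n_fp = replace_na(.data$n, 0L)) |>
    select("sample", "type", "n_fp")

  structure(
    list(thresholds = thresholds, fp_counts = fp_counts, limits = limits,
         control_samples = control_samples),
    class = "fp_calibration"
  )
}

#' @export
print.fp_calibration <- function(x, ...) {
  cat("<fp_calibration> thresholds: ",
      paste0(names(x$thresholds), " = ", signif(x$thresholds, 4),
             collapse = ", "), "\n", sep = "")
  cat("  limits per control clone: ",
      paste0(names(x$limits), " <= ", x$limits, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Call unique mutations with calibrated filtering
#'
#' Runs the full pass over a count table: candidate detection, Fisher-type
#' scoring, inclusive thresholding at the calibrated type-specific score
#' thresholds, and annotation of SNVs with their reference trinucleotide
#' context.  If no calibration is supplied it is computed on the fly from
#' `control_samples`.
#'
#' @param counts A `site_counts` tibble covering all clones jointly.
#' @param ref The `ref_genome` used for context annotation.
#' @param calibration An [calibrate_threshold()] result, or `NULL` to
#'   calibrate on `control_samples`.
#' @param control_samples Control clone ids (required if `calibration` is
#'   `NULL`); control-clone calls are excluded from the returned set when
#'   `drop_controls` is `TRUE`.
#' @param drop_controls Drop calls assigned to control clones.
#' @inheritParams detect_candidates
#' @return A tibble of class `mutation_calls`, sorted by sample, contig and
#'   position: `sample`, `contig`, `pos`, `ref`, `alt`, `type`, `score`,
#'   `vaf`, `context` (`NA` at contig edges).  The calibration used is
#'   attached as the `calibration` attribute.
#' @export
call_mutations <- function(counts, ref, calibration = NULL,
                           control_samples = NULL, drop_controls = TRUE,
                           min_vaf = 0.2, min_other_ref_freq = 0.93,
                           min_cov = 7) {
  cand <- detect_candidates(counts, min_vaf = min_vaf,
                            min_other_ref_freq = min_other_ref_freq,
                            min_cov = min_cov) |>
    score_candidates()
  if (is.null(calibration)) {
    if (is.null(control_samples)) {
      abort("supply either `calibration` or `control_samples`.")
    }
    calibration <- calibrate_threshold(cand, control_samples)
  }
  thr <- calibration$thresholds
  calls <- cand |>
    filter(.data$score >= thr[.data$type])
  if (drop_controls && !is.null(calibration$control_samples)) {
    calls <- calls |>
      filter(!.data$sample %in% calibration$control_samples)
  }
  ctx <- ref_context(ref, calls$contig, calls$pos)
  ctx[calls$type != "SNV"] <- NA_character_
  out <- calls |>
    transmute(
      sample = .data$sample, contig = .data$contig, pos = .data$pos,
      ref = .data$ref_base, alt = .data$alt, type = .data$type,
      score = .data$score, vaf = .data$vaf, context = ctx
    ) |>
    arrange(.data$sample, .data$contig, .data$pos)
  class(out) <- c("mutation_calls", class(tibble()))
  attr(out, "calibration") <- calibration
  attr(out, "skipped_sites") <- attr(cand, "skipped_sites")
  out
}
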