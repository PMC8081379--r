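#' Per-group mutation burden summary
#'
#' Counts calls per sample and mutation type, summarizes each treatment
#' group (n, mean, SEM), computes the excess burden over the matched mock
#' group of the same cell line, and tests each treated group against mock
#' with an unpaired t-test.
#'
#' @param calls A `mutation_calls` tibble.
#' @param groups Sample sheet: tibble with `sample`, `drug`, `dose` and
#'   optionally `cell_line` (defaults to a single line).  Samples with no
#'   calls contribute zero counts.
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` switches to Welch.
#' @return A tibble of class `burden_summary` with one row per
#'   (cell_line, drug, dose, type): `n`, `mean`, `sem`, `mock_mean`,
#'   `excess`, `t`, `df`, `p`.  Per-sample counts are attached as the
#'   `per_sample` attribute.
#' @export
burden_table <- function(calls, groups, var_equal = TRUE) {
  groups <- as_tibble(groups)
  stopifnot(all(c("sample", "drug", "dose") %in% names(groups)))
  if (!"cell_line" %in% names(groups)) groups$cell_line <- "line1"
  if (anyDuplicated(groups$sample)) {
    abort("every sample must belong to exactly one group.")
  }
  types <- c("SNV", "INS", "DEL")
  per_sample <- calls |>
    filter(.data$sample %in% groups$sample) |>
    count(.data$sample, .data$type, name = "count") |>
    right_join(crossing(sample = groups$sample, type = types),
               by = c("sample", "type")) |>
    mutate(count = replace_na(.data$count, 0L)) |>
    inner_join(groups, by = "sample")

  summ <- per_sample |>
    group_by(.data$cell_line, .data$drug, .data$dose, .data$type) |>
    summarise(
      n = n(), mean = mean(.data$count),
      sem = ifelse(n() > 1, sd(.data$count) / sqrt(n()), NA_real_),
      .groups = "drop"
    )

  mock <- summ |>
    filter(.data$drug == "mock") |>
    select("cell_line", "type", mock_mean = "mean")
  summ <- summ |>
    left_join(mock, by = c("cell_line", "type")) |>
    mutate(excess = ifelse(.data$drug == "mock", NA_real_,
                           .data$mean - .data$mock_mean))

  test_one <- function(cell_line, drug, dose, type) {
    if (drug == "mock") return(tibble(t = NA_real_, df = NA_real_, p = NA_real_))
    a <- per_sample$count[per_sample$cell_line == cell_line &
                            per_sample$drug == drug &
                            per_sample$dose == dose &
                            per_sample$type == type]
    b <- per_sample$count[per_sample$cell_line == cell_line &
                            per_sample$drug == "mock" &
                            per_sample$type == type]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble(t = NA_real_, df = NA_real_, p = NA_real_))
    }
    r <- unpaired_t(a, b, var_equal = var_equal)
    tibble(t = r$t, df = r$df, p = r$p)
  }
  tests <- summ |>
    select("cell_line", "drug", "dose", "type") |>
    pmap(test_one) |>
    bind_rows()
  out <- bind_cols(summ, tests)
  class(out) <- c("burden_summary", class(tibble()))
  attr(out, "per_sample") <- per_sample
  attr(out, "var_equal") <- var_equal
  out
}

#' Relative mutagenicity of a drug versus a reference drug
#'
#' `100 * excess_drug / excess_reference`, reported both unrounded and
#' rounded to the nearest integer percent.
#'
#' @param excess_drug Excess mutation count of the drug over mock.
#' @param excess_reference Excess of the reference drug (must be > 0).
#' @return A tibble with `percent` (unrounded) and `percent_rounded`.
#' @export
#' @examples
#' relative_mutagenicity(324, 532)  # 61%
#' relative_mutagenicity(207, 532)  # 39%
relative_mutagenicity <- function(excess_drug, excess_reference) {
  if (any(excess_reference <= 0)) {
    abort("`excess_reference` must be positive.")
  }
  pct <- 100 * excess_drug / excess_reference
  tibble(percent = pct, percent_rounded = round(pct))
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance Student's t-test by default (`df = nA + nB - 2`),
#' two-sided; `var_equal = FALSE` gives the Welch test.  Degenerate inputs
#' (zero pooled variance) are handled explicitly: equal means give `t = 0,
#' p = 1`; unequal means give an infinite statistic and `p = 0`, flagged.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
#' @examples
#' unpaired_t(c(1, 2, 3), c(4, 5, 6))
unpaired_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 samples.")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                    degenerate = FALSE))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf,
                  df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  r <- t.test(a, b, var.equal = var_equal)
  tibble(t = unname(r$statistic), df = unname(r$parameter),
         p = r$p.value, degenerate = FALSE)
}

#' Dose-dependence of group mean burdens
#'
#' Flags, per drug and mutation type, whether the group means are
#' non-decreasing with dose (mock <= IC25 <= IC50).  Ties count as
#' monotone; a missing tier yields `NA`.
#'
#' @param summary A [burden_table()] result containing mock, IC25 and IC50
#'   tiers.
#' @return A tibble with `cell_line`, `drug`, `type`, the three tier means
#'   and `monotone`.
#' @export
dose_trend <- function(summary) {
  drugs <- summary |>
    filter(.data$drug != "mock") |>
    distinct(.data$cell_line, .data$drug, .data$type)
  mean_of <- function(cell_line, drug, dose, type) {
    v <- summary$mean[summary$cell_line == cell_line &
                        summary$drug == drug & summary$dose == dose &
                        summary$type == type]
    if (length(v) == 1) v else NA_real_
  }
  mock_of <- function(cell_line, type) {
    v <- summary$mean[summary$cell_line == cell_line &
                        summary$drug == "mock" & summary$type == type]
    if (length(v) == 1) v else NA_real_
  }
  drugs |>
    rowwise() |>
    mutate(
      mock_mean = mock_of(.data$cell_line, .data$type),
      ic25_mean = mean_of(.data$cell_line, .data$drug, "IC25", .data$type),
      ic50_mean = mean_of(.data$cell_line, .data$drug, "IC50", .data$type),
      monotone = if (any(is.na(c(.data$mock_mean, .data$ic25_mean,
                                 .data$ic50_mean)))) NA else {
        .data$mock_mean <= .data$ic25_mean & .data$ic25_mean <= .data$ic50_mean
      }
    ) |>
    ungroup()
}
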