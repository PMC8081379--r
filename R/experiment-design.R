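#' Describe an isogenic-clone mutagenesis experiment
#'
#' Collects everything the synthetic generator needs: the treatment groups
#' with their planted burdens and direct-signature mixture weights, the
#' number of descendant clones per group, extra pre-treatment control clones
#' (replicates of the ancestor that carry no unique mutations, used for
#' false-positive calibration), and the sequencing noise model.
#'
#' @param groups A data frame with one row per treatment group and columns
#'   `drug` (e.g. `"mock"`, `"cisplatin"`), `dose` (`"mock"`, `"IC25"`,
#'   `"IC50"`), `mean_snvs` (expected planted SNVs per clone) and
#'   `direct_weight` (mixture weight of the direct platinum signature,
#'   in `[0, 1]`).  An optional `cell_line` column defaults to `"TK6"`.
#' @param clones_per_group Descendant clones per treatment group.
#' @param n_control_clones Pre-treatment control clones with zero planted
#'   mutations.
#' @param coverage_mean Mean sequencing depth per site (reads; Poisson).
#' @param seq_error_rate Per-base miscall probability, in `[0, 0.05]`.
#' @param vaf True variant allele fraction of planted mutations (0.5 for
#'   heterozygous single-site hits in a diploid genome).
#' @param noise_site_factor Clean "noise" sites emitted per planted site.
#' @param deletion_fraction Of planted indels, the fraction that are
#'   deletions.
#' @param seed Master seed; all generator randomness derives from it via
#'   [sub_seed()].
#' @return An object of class `experiment_design`.
#' @export
#' @examples
#' design <- experiment_design(
#'   groups = tibble::tibble(
#'     drug = c("mock", "cisplatin"), dose = c("mock", "IC50"),
#'     mean_snvs = c(169, 701), direct_weight = c(0, 0.6)
#'   ),
#'   clones_per_group = 3, seed = 1
#' )
experiment_design <- function(groups,
                              clones_per_group = 4,
                              n_control_clones = 3,
                              coverage_mean = 30,
                              seq_error_rate = 1e-3,
                              vaf = 0.5,
                              noise_site_factor = 10,
                              deletion_fraction = 2 / 3,
                              seed = 1) {
  groups <- as_tibble(groups)
  needed <- c("drug", "dose", "mean_snvs", "direct_weight")
  missing_cols <- setdiff(needed, names(groups))
  if (length(missing_cols) > 0) {
    abort(paste0("`groups` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"cell_line" %in% names(groups)) groups$cell_line <- "TK6"
  if (any(groups$mean_snvs < 0)) abort("`mean_snvs` must be non-negative.")
  if (any(groups$direct_weight < 0 | groups$direct_weight > 1)) {
    abort("`direct_weight` must lie in [0, 1].")
  }
  if (coverage_mean <= 0) abort("`coverage_mean` must be positive.")
  if (seq_error_rate < 0 || seq_error_rate > 0.05) {
    abort("`seq_error_rate` must lie in [0, 0.05].")
  }
  if (vaf <= 0 || vaf > 1) abort("`vaf` must lie in (0, 1].")
  if (anyDuplicated(paste(groups$cell_line, groups$drug, groups$dose))) {
    abort("duplicate (cell_line, drug, dose) rows in `groups`.")
  }
  groups$group <- paste(groups$drug, groups$dose, sep = "_")
  structure(
    list(
      groups = groups,
      clones_per_group = as.integer(clones_per_group),
      n_control_clones = as.integer(n_control_clones),
      coverage_mean = coverage_mean,
      seq_error_rate = seq_error_rate,
      vaf = vaf,
      noise_site_factor = noise_site_factor,
      deletion_fraction = deletion_fraction,
      seed = as.integer(seed)
    ),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design> ", nrow(x$groups), " groups x ",
      x$clones_per_group, " clones + ", x$n_control_clones,
      " control clones\n", sep = "")
  cat("  coverage ", x$coverage_mean, "x, error rate ", x$seq_error_rate,
      ", seed ", x$seed, "\n", sep = "")
  print(x$groups)
  invisible(x)
}

#' Sample sheet of an experiment design
#'
#' @param design An [experiment_design()].
#' @return A tibble with one row per clone: `sample`, `group`, `drug`,
#'   `dose`, `cell_line` and `role` (`"treated"`, `"mock"` or `"control"`).
#'   Control clones have `drug = "control"`.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  g <- design$groups
  clones <- crossing(group = g$group, clone = seq_len(design$clones_per_group)) |>
    left_join(g, by = "group") |>
    mutate(
      sample = paste0(.data$group, "_c", .data$clone),
      role = ifelse(.data$drug == "mock", "mock", "treated")
    ) |>
    select("sample", "group", "drug", "dose", "cell_line", "role")
  if (design$n_control_clones > 0) {
    ctrl <- tibble(
      sample = paste0("control_c", seq_len(design$n_control_clones)),
      group = "control", drug = "control", dose = "control",
      cell_line = g$cell_line[1], role = "control"
    )
    clones <- bind_rows(clones, ctrl)
  }
  clones
}

#' Demo experiment design
#'
#' A TK6-like arm of the study: a mock group at the spontaneous burden and
#' two platinum groups whose mean burdens equal mock plus the reported
#' excess SNV counts, with direct-signature mixture weights chosen so the
#' treated groups carry both the direct peaks and an elevated background.
#'
#' @param seed Master seed.
#' @return An `experiment_design`.
#' @export
demo_design <- function(seed = 1) {
  experiment_design(
    groups = tibble(
      drug = c("mock", "cisplatin", "carboplatin"),
      dose = c("mock", "IC50", "IC50"),
      mean_snvs = c(169, 701, 493),
      direct_weight = c(0, 0.6, 0.5)
    ),
    clones_per_group = 4,
    n_control_clones = 3,
    coverage_mean = 30,
    seq_error_rate = 1e-3,
    seed = seed
  )
}
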