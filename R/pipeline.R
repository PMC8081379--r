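#' Assemble and validate a pipeline configuration
#'
#' One document drives the whole pipeline.  A config with only a
#' `simulate` block is runnable end to end: every other stage has
#' defaults.  Configurations can also be read from a YAML file with
#' [read_pipeline_config()].
#'
#' @param simulate List: `length_bp`, `gene_fraction`, `gc`, `n_contigs`,
#'   plus the [experiment_design()] fields (`groups` as a data frame or
#'   list of rows, `clones_per_group`, `n_control_clones`,
#'   `coverage_mean`, `seq_error_rate`, ...).  Omit it to analyse existing
#'   files instead (then `paths$counts`, `paths$reference` and
#'   `paths$genes` are required).
#' @param paths List of input paths (used when `simulate` is absent).
#' @param caller List: `min_vaf`, `min_other_ref_freq`, `min_cov`,
#'   `snv_limit`, `ins_limit`, `del_limit`.
#' @param nmf List: `k`, `restarts`, `max_iter`, `tol`.
#' @param report List: `reference_drug`, `duration_days`, `cycle_hours`.
#' @param seed Master seed for every stage.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, caller = list(),
                            nmf = list(), report = list(), seed = 1) {
  config <- list(
    simulate = simulate, paths = paths,
    caller = modifyList(list(min_vaf = 0.2, min_other_ref_freq = 0.93,
                             min_cov = 7, snv_limit = 5, ins_limit = 1,
                             del_limit = 1), caller),
    nmf = modifyList(list(k = 2, restarts = 50, max_iter = 2000, tol = 1e-8),
                     nmf),
    report = modifyList(list(reference_drug = "cisplatin",
                             duration_days = 50, cycle_hours = 16), report),
    seed = as.integer(seed)
  )
  validate_pipeline_config(config)
  structure(config, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path A YAML file holding the same fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulate$groups)) {
    raw$simulate$groups <- bind_rows(lapply(raw$simulate$groups, as_tibble))
  }
  pipeline_config(
    simulate = raw$simulate, paths = raw$paths,
    caller = raw$caller %||% list(), nmf = raw$nmf %||% list(),
    report = raw$report %||% list(), seed = raw$seed %||% 1
  )
}

validate_pipeline_config <- function(config) {
  fail <- function(field, why) {
    abort(paste0("invalid config: field `", field, "` ", why))
  }
  if (is.null(config$simulate)) {
    for (f in c("counts", "reference")) {
      if (is.null(config$paths[[f]])) {
        fail(paste0("paths$", f), "is required when there is no simulate block")
      }
    }
  } else {
    s <- config$simulate
    if (is.null(s$length_bp)) fail("simulate$length_bp", "is required")
    if (is.null(s$groups)) fail("simulate$groups", "is required")
    g <- as_tibble(s$groups)
    for (f in c("drug", "dose", "mean_snvs", "direct_weight")) {
      if (!f %in% names(g)) fail(paste0("simulate$groups$", f), "is required")
    }
  }
  with(config$caller, {
    if (min_vaf <= 0 || min_vaf > 1) fail("caller$min_vaf", "must be in (0, 1]")
    if (min_cov < 1) fail("caller$min_cov", "must be >= 1")
  })
  if (config$nmf$k < 1) fail("nmf$k", "must be >= 1")
  invisible(TRUE)
}

#' Demo configuration
#'
#' A complete simulated experiment at desk scale: a 3 Mb genome (30% genic,
#' GC 0.42) and the [demo_design()] groups (mock plus cisplatin and
#' carboplatin at IC50, four clones each, three control clones, 30x
#' coverage, error rate 1e-3).
#'
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1) {
  d <- demo_design(seed)
  pipeline_config(
    simulate = list(
      length_bp = 3e6, gene_fraction = 0.3, gc = 0.42, n_contigs = 3,
      groups = d$groups[, c("drug", "dose", "mean_snvs", "direct_weight")],
      clones_per_group = d$clones_per_group,
      n_control_clones = d$n_control_clones,
      coverage_mean = d$coverage_mean,
      seq_error_rate = d$seq_error_rate
    ),
    nmf = list(restarts = 20),
    seed = seed
  )
}

#' Run the full pipeline from one configuration
#'
#' Executes simulate (or load) -> call -> spectra -> decompose -> report,
#' writing per-stage outputs and a manifest (file list with MD5 checksums,
#' the parameter echo, and the seeds used).  Re-running with an identical
#' config reproduces identical checksums.  If a stage fails, outputs of
#' completed stages are retained and the manifest records the failure
#' point.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- "init"
  status <- "ok"
  err_msg <- NULL

  result <- tryCatch({
    # --- stage: simulate or load ---------------------------------------
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      s <- config$simulate
      ref <- make_reference(
        length_bp = s$length_bp, gene_fraction = s$gene_fraction %||% 0.3,
        gc = s$gc %||% 0.42, seed = config$seed,
        n_contigs = s$n_contigs %||% 1
      )
      design <- experiment_design(
        groups = as_tibble(s$groups),
        clones_per_group = s$clones_per_group %||% 4,
        n_control_clones = s$n_control_clones %||% 3,
        coverage_mean = s$coverage_mean %||% 30,
        seq_error_rate = s$seq_error_rate %||% 1e-3,
        seed = config$seed
      )
      truth <- plant_mutations(ref, design)
      counts <- emit_counts(ref, truth, design)
      files <- c(files,
                 write_reference_fasta(ref, file.path(out_dir, "reference.fa"),
                                       file.path(out_dir, "genes.bed")),
                 file.path(out_dir, "genes.bed"),
                 write_truth_tsv(truth, file.path(out_dir, "truth.tsv")),
                 write_counts_tsv(counts, file.path(out_dir, "counts.tsv")))
    } else {
      stage <- "load"
      ref <- read_reference_fasta(config$paths$reference, config$paths$genes)
      counts <- read_counts_tsv(config$paths$counts)
      design <- NULL
    }

    # --- stage: call ----------------------------------------------------
    stage <- "call"
    sheet <- if (!is.null(design)) design_samples(design) else {
      tibble(sample = attr(counts, "samples"),
             group = "unknown", drug = "unknown", dose = "unknown",
             cell_line = "line1", role = "treated")
    }
    control_samples <- config$paths$controls %||%
      sheet$sample[sheet$role == "control"]
    cp <- config$caller
    cand <- detect_candidates(counts, min_vaf = cp$min_vaf,
                              min_other_ref_freq = cp$min_other_ref_freq,
                              min_cov = cp$min_cov) |>
      score_candidates()
    calibration <- calibrate_threshold(cand, control_samples,
                                       snv_limit = cp$snv_limit,
                                       ins_limit = cp$ins_limit,
                                       del_limit = cp$del_limit)
    calls <- call_mutations(counts, ref, calibration = calibration,
                            min_vaf = cp$min_vaf,
                            min_other_ref_freq = cp$min_other_ref_freq,
                            min_cov = cp$min_cov)
    files <- c(files,
               write_calls_tsv(calls, file.path(out_dir, "calls.tsv")),
               write_vcf(calls, ref, file.path(out_dir, "vcf")))
    cal_path <- file.path(out_dir, "calibration.json")
    jsonlite::write_json(
      list(thresholds = as.list(calibration$thresholds),
           limits = as.list(calibration$limits),
           fp_counts = calibration$fp_counts),
      cal_path, auto_unbox = TRUE, digits = NA
    )
    files <- c(files, cal_path)

    # --- stage: spectra -------------------------------------------------
    stage <- "spectra"
    spectra <- build_spectrum(calls)
    sb <- strand_bias(calls, ref$genes)
    files <- c(files,
               write_spectrum_tsv(spectra, file.path(out_dir, "spectra.tsv")))
    readr::write_tsv(sb, file.path(out_dir, "strand_bias.tsv"))
    files <- c(files, file.path(out_dir, "strand_bias.tsv"))

    # --- stage: decompose -----------------------------------------------
    stage <- "decompose"
    np <- config$nmf
    fit <- nmf_fit(spectra, k = np$k, restarts = np$restarts,
                   max_iter = np$max_iter, tol = np$tol, seed = config$seed)
    # resolve the rotational ambiguity of the factorization, anchoring the
    # background component on the mock clones when the design has them
    mock_samples <- intersect(sheet$sample[sheet$role == "mock"],
                              unique(calls$sample))
    fit <- resolve_components(fit, spectra,
                              background_samples =
                                if (length(mock_samples) > 0) mock_samples)
    files <- c(files,
               write_signatures_tsv(fit, file.path(out_dir, "signatures.tsv")),
               write_exposures_tsv(fit, file.path(out_dir, "exposures.tsv")))

    # --- stage: report --------------------------------------------------
    stage <- "report"
    groups <- sheet |> filter(.data$role != "control")
    burden <- burden_table(calls, groups)
    rp <- config$report
    ref_drug <- rp$reference_drug
    rel <- NULL
    exc <- burden |>
      filter(.data$type == "SNV", .data$drug != "mock") |>
      select("drug", "dose", "excess")
    if (ref_drug %in% exc$drug) {
      ref_excess <- exc$excess[exc$drug == ref_drug][1]
      if (is.finite(ref_excess) && ref_excess > 0) {
        rel <- exc |>
          mutate(relative_mutagenicity(.data$excess, ref_excess))
      }
    }
    genome_gb <- sum(nchar(ref$contigs)) / 1e9
    mock_counts <- attr(burden, "per_sample") |>
      filter(.data$drug == "mock", .data$type == "SNV")
    rate <- if (nrow(mock_counts) > 0) {
      mutation_rate(mean(mock_counts$count), rp$duration_days,
                    rp$cycle_hours, genome_gb)
    } else NULL
    expo <- exposures_by_group(
      fit, groups |> select("sample", "group")
    )
    report <- list(
      burden = as_tibble(burden),
      relative_mutagenicity = rel,
      spontaneous_rate = rate,
      exposures_by_group = expo,
      dose_trend = tryCatch(dose_trend(burden), error = function(e) NULL),
      nmf = glance.mut_nmf(fit)
    )
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    files <- c(files, report_path)
    stage <- "done"
    list(calls = calls, spectra = spectra, fit = fit, burden = burden,
         calibration = calibration)
  }, error = function(e) {
    status <<- "failed"
    err_msg <<- conditionMessage(e)
    NULL
  })

  files <- unique(files[file.exists(files)])
  manifest <- list(
    status = status,
    failed_stage = if (status == "failed") stage else NULL,
    error = err_msg,
    seed = config$seed,
    parameters = unclass(config),
    files = tibble(
      file = ifelse(startsWith(files, paste0(out_dir, "/")),
                    substring(files, nchar(out_dir) + 2), files),
      md5 = unname(tools::md5sum(files))
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  if (status == "failed") {
    warn(paste0("pipeline failed at stage `", stage, "`: ", err_msg,
                " (partial outputs retained)"))
  }
  invisible(c(result, list(manifest = manifest, out_dir = out_dir)))
}
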