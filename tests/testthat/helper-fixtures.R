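# Shared fixtures, all generated in code at test time.

# A signature concentrating all mass on one channel.
sig_point <- function(channel, ts_bias = 0.5, indel_rate = 0) {
  p <- rep(0, 96)
  p[match(channel, sbs_channels()$channel)] <- 1
  signature_spec(p, ts_bias = ts_bias, indel_rate = indel_rate,
                 name = paste0("point:", channel))
}

# Build one site of a long-form counts table by hand.
# alt_n: named per-sample alternate-base read counts (base given by `alt`).
mk_site <- function(samples, cov, ref, alt = NULL, alt_n = 0,
                    pos = 100L, contig = "chr1", ins_n = 0, del_n = 0) {
  n <- length(samples)
  cov <- rep_len(cov, n)
  alt_n <- rep_len(alt_n, n)
  ins_n <- rep_len(ins_n, n)
  del_n <- rep_len(del_n, n)
  bm <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  bm[, ref] <- as.integer(cov - alt_n)
  if (!is.null(alt)) bm[, alt] <- as.integer(alt_n)
  tibble::tibble(
    contig = contig, pos = as.integer(pos), ref_base = ref,
    sample = samples, cov = as.integer(cov),
    A = bm[, "A"], C = bm[, "C"], G = bm[, "G"], T = bm[, "T"],
    ins_support = as.integer(ins_n), del_support = as.integer(del_n)
  )
}

# Turn planted truth into the minimal calls shape the spectrum/strand-bias
# functions expect.
truth_as_calls <- function(truth, genome) {
  ctx <- ref_context(genome, truth$contig, truth$pos)
  dplyr::mutate(
    truth,
    sample = .data$clone,
    ref = substr(.data$ref, 1, 1),
    alt = ifelse(.data$type == "SNV", .data$alt, paste0("<", .data$type, ">")),
    context = ctx,
    score = 100, vaf = 0.5
  )
}

# A small complete experiment reused by several calling tests.
small_run <- function(seq_error_rate = 0, mean_snvs = 200, seed = 11,
                      clones = 2, controls = 2, length_bp = 100000) {
  ref <- make_reference(length_bp, gene_fraction = 0.3, gc = 0.45, seed = seed)
  design <- experiment_design(
    groups = tibble::tibble(drug = "cisplatin", dose = "IC50",
                            mean_snvs = mean_snvs, direct_weight = 0.5),
    clones_per_group = clones, n_control_clones = controls,
    seq_error_rate = seq_error_rate, seed = seed
  )
  truth <- plant_mutations(ref, design)
  counts <- emit_counts(ref, truth, design)
  list(ref = ref, design = design, truth = truth, counts = counts)
}

truth_key <- function(truth) {
  paste(truth$clone, truth$contig, truth$pos, truth$type)
}

call_key <- function(calls) {
  paste(calls$sample, calls$contig, calls$pos, calls$type)
}
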