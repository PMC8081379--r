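test_that("make_reference is deterministic with controlled GC and gene content", {
  ref1 <- make_reference(100000, gene_fraction = 0.3, gc = 0.5, seed = 1)
  ref2 <- make_reference(100000, gene_fraction = 0.3, gc = 0.5, seed = 1)
  expect_identical(ref1, ref2)

  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_reference_fasta(ref1, f1)
  write_reference_fasta(ref2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  seqs <- strsplit(ref1$contigs[[1]], "")[[1]]
  expect_equal(sum(nchar(ref1$contigs)), 100000)
  gc_obs <- mean(seqs %in% c("G", "C"))
  expect_gt(gc_obs, 0.45)
  expect_lt(gc_obs, 0.55)

  # genes: within bounds, non-overlapping
  g <- ref1$genes
  expect_true(all(g$start >= 0 & g$end <= nchar(ref1$contigs[g$contig])))
  g <- g[order(g$start), ]
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))

  expect_equal(nrow(make_reference(20000, gene_fraction = 0, seed = 2)$genes), 0)
  expect_error(make_reference(5000), "at least 10000")
  expect_error(make_reference(20000, gc = 0), "strictly between")
})

test_that("degenerate planting puts every SNV in the requested context", {
  ref <- make_reference(50000, gene_fraction = 0.2, seed = 3)
  design <- experiment_design(
    groups = tibble::tibble(drug = "cisplatin", dose = "IC50",
                            mean_snvs = 150, direct_weight = 1),
    clones_per_group = 2, n_control_clones = 0, seed = 3
  )
  truth <- plant_mutations(ref, design, direct = sig_point("A[C>A]C"))
  snv <- truth[truth$type == "SNV", ]
  expect_gt(nrow(snv), 0)
  expect_true(all(snv$channel == "A[C>A]C"))
  # on the reference strand the site is either ACC (C>A) or its reverse
  # complement GGT (G>T)
  ctx <- ref_context(ref, snv$contig, snv$pos)
  plus <- snv$pyr_strand == "+"
  expect_true(all(ctx[plus] == "ACC" & snv$ref[plus] == "C" & snv$alt[plus] == "A"))
  expect_true(all(ctx[!plus] == "GGT" & snv$ref[!plus] == "G" & snv$alt[!plus] == "T"))
})

test_that("planted truth is unique per clone, matches the reference, and mock stays clean", {
  run <- small_run(mean_snvs = 150, seed = 5)
  truth <- run$truth
  expect_equal(anyDuplicated(paste(truth$contig, truth$pos)), 0)
  expect_true(all(substr(truth$ref, 1, 1) ==
                    platmut:::ref_base_at(run$ref, truth$contig, truth$pos)))

  design0 <- experiment_design(
    groups = tibble::tibble(drug = "mock", dose = "mock",
                            mean_snvs = 0, direct_weight = 0),
    clones_per_group = 3, n_control_clones = 0, seed = 5
  )
  truth0 <- plant_mutations(run$ref, design0,
                            direct = platinum_signature(indel_rate = 0),
                            background = background_signature(indel_rate = 0))
  expect_equal(nrow(truth0), 0)
})

test_that("planted channel frequencies follow the signature and the mixture", {
  ref <- make_reference(500000, gene_fraction = 0.3, seed = 7)
  design <- experiment_design(
    groups = tibble::tibble(
      drug = c("pure_bg", "mixed"), dose = c("IC25", "IC50"),
      mean_snvs = c(10000, 10000), direct_weight = c(0, 0.5)
    ),
    clones_per_group = 1, n_control_clones = 0, seed = 7
  )
  direct <- platinum_signature(indel_rate = 0)
  bg <- background_signature(indel_rate = 0)
  truth <- plant_mutations(ref, design, direct = direct, background = bg)

  # pure background clone: per-channel binomial check, 3 standard errors
  t1 <- truth[truth$clone == "pure_bg_IC25_c1", ]
  n1 <- nrow(t1)
  expect_gt(n1, 9000)
  emp <- tabulate(match(t1$channel, sbs_channels()$channel), 96) / n1
  p <- unname(bg$channel_probs)
  se <- sqrt(p * (1 - p) / n1)
  expect_true(all(abs(emp - p) <= 3 * se + 1e-12))

  # 50/50 mixture: total-variation distance to the planted mixture
  t2 <- truth[truth$clone == "mixed_IC50_c1", ]
  emp2 <- tabulate(match(t2$channel, sbs_channels()$channel), 96) / nrow(t2)
  mix <- 0.5 * unname(direct$channel_probs) + 0.5 * p
  tv <- 0.5 * sum(abs(emp2 - mix))
  expect_lt(tv, 0.05)
})

test_that("emit_counts has the promised noise model and is deterministic", {
  run <- small_run(seq_error_rate = 0, mean_snvs = 100, seed = 9)
  counts <- run$counts
  truth <- run$truth

  # with zero error rate, clean sites carry no alternate reads at all
  planted <- paste(truth$contig, truth$pos)
  clean <- counts[!(paste(counts$contig, counts$pos) %in% planted), ]
  bm <- as.matrix(clean[, c("A", "C", "G", "T")])
  ref_n <- bm[cbind(seq_len(nrow(clean)), match(clean$ref_base, c("A", "C", "G", "T")))]
  expect_true(all(rowSums(bm) == ref_n))
  expect_true(all(clean$ins_support == 0))
  expect_true(all(clean$del_support == 0))
  expect_true(all(rowSums(bm) == clean$cov))

  counts2 <- emit_counts(run$ref, truth, run$design)
  expect_identical(as.data.frame(counts), as.data.frame(counts2))
})

test_that("planted heterozygous SNVs have mean VAF near 0.5", {
  ref <- make_reference(500000, gene_fraction = 0, seed = 13)
  design <- experiment_design(
    groups = tibble::tibble(drug = "d", dose = "IC50",
                            mean_snvs = 1000, direct_weight = 0.5),
    clones_per_group = 1, n_control_clones = 1,
    seq_error_rate = 0, seed = 13
  )
  truth <- plant_mutations(ref, design,
                           direct = platinum_signature(indel_rate = 0),
                           background = background_signature(indel_rate = 0))
  counts <- emit_counts(ref, truth, design, noise_sites = 0)
  hit <- dplyr::inner_join(
    counts, dplyr::select(truth, contig, pos, sample = clone, alt),
    by = c("contig", "pos", "sample")
  )
  bm <- as.matrix(hit[, c("A", "C", "G", "T")])
  alt_n <- bm[cbind(seq_len(nrow(hit)), match(hit$alt, c("A", "C", "G", "T")))]
  vaf <- alt_n / hit$cov
  expect_gt(nrow(hit), 900)
  expect_gt(mean(vaf), 0.48)
  expect_lt(mean(vaf), 0.52)
})
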