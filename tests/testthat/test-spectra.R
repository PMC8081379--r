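toy_ref <- function(seq) {
  structure(list(
    contigs = c(chr1 = seq),
    genes = tibble::tibble(contig = character(), start = integer(),
                           end = integer(), strand = character(),
                           gene_id = character())
  ), class = "ref_genome")
}

mk_calls <- function(pos, ref, alt, context, sample = "s1", type = "SNV",
                     contig = "chr1") {
  tibble::tibble(sample = sample, contig = contig, pos = as.integer(pos),
                 ref = ref, alt = alt, type = type, score = 50, vaf = 0.5,
                 context = context)
}

test_that("build_spectrum tallies, averages and reconciles drops", {
  calls <- mk_calls(10, "C", "T", "ACG")
  sp <- build_spectrum(calls)
  expect_equal(sum(sp$count), 1)
  expect_equal(sp$count[sp$channel == "A[C>T]G"], 1L)

  # averaging two identical samples equals either one
  two <- dplyr::bind_rows(calls, dplyr::mutate(calls, sample = "s2"))
  avg <- build_spectrum(two, groups = tibble::tibble(
    sample = c("s1", "s2"), group = "g"), mode = "average")
  expect_equal(avg$count[avg$channel == "A[C>T]G"], 1)
  expect_equal(sum(avg$count), 1)

  # context-unresolvable calls are dropped and counted
  with_edge <- dplyr::bind_rows(calls, mk_calls(1, "C", "A", NA))
  sp2 <- build_spectrum(with_edge)
  expect_equal(sum(sp2$count), 1)
  expect_equal(attr(sp2, "dropped"), 1L)

  expect_error(build_spectrum(calls, groups = tibble::tibble(
    sample = character(), group = character())), "no samples")
})

test_that("spectra and strand bias are invariant under reverse-complementing the reference", {
  run <- small_run(mean_snvs = 300, seed = 23)
  calls <- truth_as_calls(run$truth, run$ref) |>
    dplyr::filter(type == "SNV")
  L <- nchar(run$ref$contigs[[1]])

  calls_rc <- calls |>
    dplyr::mutate(
      pos = L + 1L - pos,
      ref = chartr("ACGT", "TGCA", ref),
      alt = chartr("ACGT", "TGCA", alt),
      context = revcomp(context)
    )
  genes_rc <- run$ref$genes |>
    dplyr::mutate(
      start2 = L - end, end = L - start, start = start2,
      strand = ifelse(strand == "+", "-", "+")
    ) |>
    dplyr::select(-start2)

  sp <- build_spectrum(calls)
  sp_rc <- build_spectrum(calls_rc)
  expect_equal(sp$count, sp_rc$count)

  sb <- strand_bias(calls, run$ref$genes)
  sb_rc <- strand_bias(calls_rc, genes_rc)
  expect_equal(sb$transcribed, sb_rc$transcribed)
  expect_equal(sb$untranscribed, sb_rc$untranscribed)
})

test_that("strand bias matches the exact binomial oracle", {
  # one gene on the + strand covering the whole contig; pyrimidine on the -
  # strand means the mutation is counted as transcribed
  genes <- tibble::tibble(contig = "chr1", start = 0L, end = 10000L,
                          strand = "+", gene_id = "g1")
  ts <- mk_calls(seq(10, by = 3, length.out = 30), "G", "T", "AGA")
  uts <- mk_calls(seq(1000, by = 3, length.out = 10), "C", "A", "ACA")
  sb <- strand_bias(dplyr::bind_rows(ts, uts), genes)
  expect_equal(sb$transcribed, 30L)
  expect_equal(sb$untranscribed, 10L)
  expect_equal(sb$ratio, 3)
  p_oracle <- sum(dbinom(c(0:10, 30:40), 40, 0.5))
  expect_equal(sb$p_value, p_oracle, tolerance = 1e-12)

  balanced <- strand_bias(
    dplyr::bind_rows(ts[1:10, ], uts), genes)
  expect_equal(balanced$ratio, 1)
  expect_equal(balanced$p_value, 1)

  # intergenic-only calls yield an empty table
  empty <- strand_bias(ts, genes[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("the generator's transcribed-strand bias is recovered by strand_bias", {
  ref <- make_reference(200000, gene_fraction = 0.5, seed = 29)
  design <- experiment_design(
    groups = tibble::tibble(drug = "cisplatin", dose = "IC50",
                            mean_snvs = 800, direct_weight = 1),
    clones_per_group = 1, n_control_clones = 0, seed = 29
  )
  truth <- plant_mutations(ref, design,
                           direct = platinum_signature(ts_bias = 0.8,
                                                       indel_rate = 0))
  calls <- truth_as_calls(truth, ref)
  expect_gte(sum(truth$in_gene), 200)
  sb <- strand_bias(calls, ref$genes)
  ca <- sb[sb$class == "C>A", ]
  expect_gt(ca$transcribed, ca$untranscribed)
  expect_lt(ca$p_value, 0.01)
})

test_that("adjacent SNVs merge into canonical doublets and triples are excluded", {
  pair <- dplyr::bind_rows(
    mk_calls(100, "C", "A", "ACC"),
    mk_calls(101, "C", "A", "CCT")
  )
  dbs <- classify_dbs(pair)
  expect_equal(nrow(dbs), 1)
  expect_equal(dbs$dbs, "CC>AA")

  # reverse-complement representation normalizes into the canonical set
  pair_rc <- dplyr::bind_rows(
    mk_calls(200, "G", "T", "AGG"),
    mk_calls(201, "G", "T", "GGT")
  )
  expect_equal(classify_dbs(pair_rc)$dbs, "CC>AA")

  expect_equal(nrow(classify_dbs(mk_calls(c(10, 20, 30), "C", "A", "ACA"))), 0)

  triple <- mk_calls(300:302, "C", "A", "CCC")
  d3 <- classify_dbs(triple)
  expect_equal(nrow(d3), 0)
  expect_equal(attr(d3, "mnv_excluded"), 1L)

  # expected adjacent-pair count among uniform positions: ~n^2/L
  set.seed(31)
  L <- 200000; n <- 2000
  pos <- sort(sample.int(L, n))
  unif <- mk_calls(pos, "C", "A", "ACA")
  got <- nrow(classify_dbs(unif))
  expected <- n^2 / L
  expect_gt(got, expected - 3 * sqrt(expected) - 2)
  expect_lt(got, expected + 3 * sqrt(expected) + 2)
})

test_that("indels are classified by length and homopolymer run, invariant under reverse complement", {
  seqs <- "GGTAAAAATGGCATGCA"
  ref <- toy_ref(seqs)
  del <- tibble::tibble(sample = "s1", contig = "chr1", pos = 3L,
                        ref = "TA", alt = "T", type = "DEL")
  cl <- classify_indel(del, ref)
  expect_equal(cl$indel_len, 1L)
  expect_equal(cl$len_bucket, "1")
  expect_equal(cl$homopolymer_run, 5L)
  expect_equal(cl$run_bucket, "5+")

  ins <- tibble::tibble(sample = "s1", contig = "chr1", pos = 12L,
                        ref = "A", alt = "ACGT", type = "INS")
  cl2 <- classify_indel(ins, ref)
  expect_equal(cl2$len_bucket, "2-4")
  expect_equal(cl2$run_bucket, "0-1")

  # same deletion seen from the reverse-complemented locus
  L <- nchar(seqs)
  ref_rc <- toy_ref(revcomp(seqs))
  del_rc <- tibble::tibble(sample = "s1", contig = "chr1",
                           pos = L - 4L + 1L - 1L,  # anchor left of comp base
                           ref = substr(revcomp(seqs), L - 4L, L - 3L),
                           alt = substr(revcomp(seqs), L - 4L, L - 4L),
                           type = "DEL")
  cl_rc <- classify_indel(del_rc, ref_rc)
  expect_equal(cl_rc$homopolymer_run, cl$homopolymer_run)
  expect_equal(cl_rc$run_bucket, cl$run_bucket)

  expect_error(
    classify_indel(tibble::tibble(sample = "s", contig = "chr1", pos = 3L,
                                  ref = "T", alt = "<INS>", type = "INS"),
                   ref),
    "symbolic"
  )
})

test_that("mutation_rate reproduces the spontaneous-rate arithmetic and is linear", {
  r <- mutation_rate(169, 50, 16, 3.0)
  expect_equal(r$cycles, 75)
  expect_equal(round(r$rate_per_gb_per_cycle, 2), 0.75)

  expect_equal(mutation_rate(0, 50, 16, 3)$rate_per_gb_per_cycle, 0)
  expect_equal(mutation_rate(75, 50, 16, 1)$rate_per_gb_per_cycle, 1)

  base <- mutation_rate(100, 50, 16, 3)$rate_per_gb_per_cycle
  expect_equal(mutation_rate(200, 50, 16, 3)$rate_per_gb_per_cycle, 2 * base)
  expect_equal(mutation_rate(100, 50, 16, 6)$rate_per_gb_per_cycle, base / 2)
  expect_equal(mutation_rate(100, 100, 16, 3)$rate_per_gb_per_cycle, base / 2)
  expect_error(mutation_rate(10, 0, 16, 3), "positive")
})
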