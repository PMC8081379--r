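# Brute-force one-sided Fisher tail: P(X >= a) for the 2x2 table
# [a r; oa orf] with fixed margins, by explicit hypergeometric summation.
fisher_tail_oracle <- function(a, r, oa, orf) {
  K <- a + oa          # total alternate reads
  N <- a + r + oa + orf
  n1 <- a + r          # mutated sample depth
  xs <- max(0, n1 - (N - K)):min(K, n1)
  xs <- xs[xs >= a]
  if (length(xs) == 0) return(0)
  sum(choose(K, xs) * choose(N - K, n1 - xs)) / choose(N, n1)
}

samples5 <- paste0("s", 1:5)

test_that("detect_candidates finds unique variants and rejects shared or noisy ones", {
  # clear het in one sample, four clean others
  counts <- mk_site(samples5, cov = 30, ref = "C", alt = "A",
                    alt_n = c(15, 0, 0, 0, 0))
  cand <- detect_candidates(counts)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$sample, "s1")
  expect_equal(cand$type, "SNV")
  expect_equal(cand$alt, "A")
  expect_equal(cand$vaf, 0.5)

  # two samples with the variant: not unique
  counts2 <- mk_site(samples5, cov = 30, ref = "C", alt = "A",
                     alt_n = c(15, 15, 0, 0, 0))
  expect_equal(nrow(detect_candidates(counts2)), 0)

  # another sample fails the reference-frequency floor: 27/30 = 0.9 < 0.93
  counts3 <- mk_site(samples5, cov = 30, ref = "C", alt = "A",
                     alt_n = c(15, 3, 0, 0, 0))
  expect_equal(nrow(detect_candidates(counts3)), 0)

  # shared ancestral variant in all samples is never a candidate
  counts4 <- mk_site(samples5, cov = 30, ref = "G", alt = "T", alt_n = 15)
  expect_equal(nrow(detect_candidates(counts4)), 0)
})

test_that("detect_candidates picks the noisiest clean sample for comparison and skips zero-coverage sites", {
  counts <- dplyr::bind_rows(
    mk_site(samples5, cov = 30, ref = "C", alt = "A",
            alt_n = c(15, 0, 2, 1, 0), pos = 100),
    mk_site(samples5, cov = c(30, 0, 30, 30, 30), ref = "C", alt = "A",
            alt_n = c(15, 0, 0, 0, 0), pos = 200)
  )
  cand <- detect_candidates(counts)
  expect_equal(nrow(cand), 1)           # pos 200 skipped: a sample has cov 0
  expect_equal(cand$pos, 100L)
  expect_equal(cand$other_sample, "s3")  # lowest ref freq among the others
  expect_equal(cand$other_alt, 2L)
  expect_equal(attr(cand, "skipped_sites"), 1L)
})

test_that("indel candidates use supporting-read fractions", {
  counts <- mk_site(samples5, cov = 30, ref = "C",
                    ins_n = c(14, 0, 0, 0, 0), pos = 300)
  cand <- detect_candidates(counts)
  expect_equal(cand$type, "INS")
  expect_equal(cand$alt, "<INS>")
  expect_equal(cand$alt_count, 14L)
  expect_equal(cand$ref_count, 16L)
})

test_that("candidate scores match brute-force hypergeometric enumeration", {
  counts <- mk_site(samples5, cov = 30, ref = "C", alt = "A",
                    alt_n = c(15, 0, 0, 0, 0))
  sc <- score_candidates(detect_candidates(counts))
  expect_equal(sc$score, -log10(fisher_tail_oracle(15, 15, 0, 30)),
               tolerance = 1e-12)

  # identical tables: maximal one-sided tail >= 0.5, score below log10(2)
  counts_eq <- mk_site(samples5, cov = 30, ref = "C", alt = "A",
                       alt_n = c(16, 15, 0, 0, 0),
                       pos = 400)
  # make s1 the unique candidate but compare a nearly identical table directly
  tbl <- tibble::tibble(alt_count = 15, ref_count = 15, other_alt = 15,
                        other_ref = 15, other_zero_cov = FALSE)
  sc_eq <- score_candidates(tbl)
  expect_equal(sc_eq$score, -log10(fisher_tail_oracle(15, 15, 15, 15)),
               tolerance = 1e-12)
  expect_lt(sc_eq$score, 0.31)

  # monotonicity: more alternate reads in the comparison sample never
  # increases the score
  grid <- tibble::tibble(alt_count = 15, ref_count = 15, other_alt = 0:10,
                         other_ref = 30 - 0:10, other_zero_cov = FALSE)
  sc_m <- score_candidates(grid)
  expect_true(all(diff(sc_m$score) <= 1e-12))

  # zero-coverage comparison sample: uninformative, flagged
  tbl0 <- tibble::tibble(alt_count = 15, ref_count = 15, other_alt = 0,
                         other_ref = 0, other_zero_cov = TRUE)
  sc0 <- score_candidates(tbl0)
  expect_equal(sc0$score, 0)
  expect_true(sc0$score_flagged)
})

test_that("calibration sweeps observed scores to the smallest threshold meeting the FP bounds", {
  calls <- tibble::tibble(
    sample = "ctrl1", type = "SNV",
    score = c(1.2, 2.0, 3.5, 4.0, 4.1, 4.2, 9.9)
  )
  cal <- calibrate_threshold(calls, "ctrl1")
  # inclusive >=: T = 3.5 leaves exactly 5 calls
  expect_equal(unname(cal$thresholds["SNV"]), 3.5)
  expect_equal(cal$fp_counts$n_fp[cal$fp_counts$type == "SNV"], 5L)

  # no control calls at all: thresholds 0
  none <- calls[0, ]
  cal0 <- calibrate_threshold(none, c("c1", "c2"))
  expect_equal(unname(cal0$thresholds), c(0, 0, 0))

  # all scores equal, count within the bound: threshold equals that score
  eq5 <- tibble::tibble(sample = "c1", type = "SNV", score = rep(7, 5))
  expect_equal(unname(calibrate_threshold(eq5, "c1")$thresholds["SNV"]), 0)
  # count above the bound: just above that score
  eq7 <- tibble::tibble(sample = "c1", type = "SNV", score = rep(7, 7))
  thr <- unname(calibrate_threshold(eq7, "c1")$thresholds["SNV"])
  expect_gt(thr, 7)
  expect_lt(thr, 7 + 1e-6)

  # per-type limits: 2 insertions at one score need a higher threshold
  ins <- tibble::tibble(sample = "c1", type = "INS", score = c(3, 5))
  expect_equal(unname(calibrate_threshold(ins, "c1")$thresholds["INS"]), 5)

  expect_error(calibrate_threshold(calls, character(0)), "control")
})

test_that("zero-noise runs are called with perfect precision and near-perfect sensitivity", {
  run <- small_run(seq_error_rate = 0, mean_snvs = 200, seed = 17)
  calls <- call_mutations(run$counts, run$ref,
                          control_samples = c("control_c1", "control_c2"))
  expect_gt(nrow(calls), 0)
  expect_true(all(call_key(calls) %in% truth_key(run$truth)))  # precision 1
  snv_truth <- run$truth[run$truth$type == "SNV", ]
  recovered <- mean(truth_key(snv_truth) %in% call_key(calls))
  expect_gte(recovered, 0.99)
  # calls annotated and ordered
  expect_true(all(nchar(calls$context[calls$type == "SNV"]) == 3))
  expect_identical(order(calls$sample, calls$contig, calls$pos),
                   seq_len(nrow(calls)))
})

test_that("calling is deterministic and respects calibration thresholds by construction", {
  run <- small_run(seq_error_rate = 1e-3, mean_snvs = 150, seed = 19)
  ctrl <- c("control_c1", "control_c2")
  cand <- score_candidates(detect_candidates(run$counts))
  cal <- calibrate_threshold(cand, ctrl)
  surviving <- cand |>
    dplyr::filter(sample %in% ctrl, score >= cal$thresholds[type]) |>
    dplyr::count(sample, type)
  lim <- c(SNV = 5, INS = 1, DEL = 1)
  expect_true(all(surviving$n <= lim[surviving$type]))

  c1 <- call_mutations(run$counts, run$ref, calibration = cal)
  c2 <- call_mutations(run$counts, run$ref, calibration = cal)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})
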