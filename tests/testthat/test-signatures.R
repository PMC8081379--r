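# Draw a spectrum matrix directly from a signature mixture (multinomial
# channel draws), independent of the genome-level generator.
mixture_matrix <- function(weights, totals, direct, background, seed) {
  stopifnot(length(weights) == length(totals))
  withr::with_seed(seed, {
    V <- vapply(seq_along(weights), function(i) {
      p <- weights[i] * direct + (1 - weights[i]) * background
      as.numeric(rmultinom(1, totals[i], p))
    }, numeric(96))
  })
  dimnames(V) <- list(sbs_channels()$channel,
                      paste0("s", seq_along(weights)))
  V
}

test_that("rank-1 data is recovered exactly", {
  s <- platinum_signature()$channel_probs
  e <- c(500, 800, 1200, 650)
  V <- outer(unname(s), e)
  dimnames(V) <- list(sbs_channels()$channel, paste0("s", 1:4))
  fit <- nmf_fit(V, k = 1, restarts = 3, seed = 1)
  expect_gte(cosine_similarity(fit$signatures[, 1], unname(s)), 0.9999)
  expect_lt(fit$divergence, 1e-6)
  expect_equal(unname(colSums(fit$exposures)), e, tolerance = 1e-4)
})

test_that("divergence is monotone within a run and minimal across restarts", {
  V <- mixture_matrix(c(0, 0.3, 0.6, 0.8), rep(800, 4),
                      platinum_signature()$channel_probs,
                      background_signature()$channel_probs, seed = 3)
  fit <- nmf_fit(V, k = 2, restarts = 4, seed = 5, track_divergence = TRUE)
  tr <- fit$divergence_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(abs(tr[-length(tr)]), 1)))
  expect_true(all(fit$restart_divergences >= fit$divergence - 1e-9))
})

test_that("NMF is deterministic given the seed", {
  V <- mixture_matrix(c(0.1, 0.5, 0.7), rep(500, 3),
                      platinum_signature()$channel_probs,
                      background_signature()$channel_probs, seed = 7)
  f1 <- nmf_fit(V, k = 2, restarts = 3, seed = 9)
  f2 <- nmf_fit(V, k = 2, restarts = 3, seed = 9)
  expect_identical(f1$signatures, f2$signatures)
  expect_identical(f1$exposures, f2$exposures)
})

test_that("noiseless rank-2 mixtures with distinct supports are recovered", {
  # two signatures with disjoint supports and 20 samples of >= 500 mutations
  p1 <- rep(0, 96); p1[1:20] <- c(5, rep(1, 19)); p1 <- p1 / sum(p1)
  p2 <- rep(0, 96); p2[41:96] <- rep(1, 56); p2 <- p2 / sum(p2)
  w <- seq(0.05, 0.95, length.out = 20)
  totals <- rep(1000, 20)
  V <- vapply(seq_along(w), function(i) {
    totals[i] * (w[i] * p1 + (1 - w[i]) * p2)  # exact, no sampling noise
  }, numeric(96))
  dimnames(V) <- list(sbs_channels()$channel, paste0("s", 1:20))
  fit <- nmf_fit(V, k = 2, restarts = 8, seed = 11)
  mc <- match_components(fit$signatures, cbind(sig1 = p1, sig2 = p2))
  expect_true(all(mc$cosine >= 0.99))
  # exposure mass conservation on a well-fit dataset
  expect_true(all(abs(colSums(fit$exposures) / colSums(V) - 1) <= 0.02))
})

test_that("input validation rejects malformed spectra and ranks", {
  V <- mixture_matrix(c(0.2, 0.8), c(300, 300),
                      platinum_signature()$channel_probs,
                      background_signature()$channel_probs, seed = 13)
  expect_error(nmf_fit(V, k = 3), "k")
  V0 <- V; V0[, 2] <- 0
  expect_error(nmf_fit(V0, k = 1), "all-zero")
  Vneg <- V; Vneg[1, 1] <- -1
  expect_error(nmf_fit(Vneg, k = 1), "non-negative")
})

test_that("pick_rank reports divergence and restart stability honestly", {
  V <- mixture_matrix(c(0, 0.2, 0.4, 0.6, 0.8, 0.1, 0.5, 0.7),
                      rep(1500, 8),
                      platinum_signature()$channel_probs,
                      background_signature()$channel_probs, seed = 17)
  tab <- pick_rank(V, k_candidates = 2:3, restarts = 4, seed = 19)
  expect_equal(tab$k, 2:3)
  expect_gt(tab$stability[1], tab$stability[2])  # planted rank wins

  s <- background_signature()$channel_probs
  V1 <- outer(unname(s), c(400, 700))
  rownames(V1) <- sbs_channels()$channel
  tab1 <- pick_rank(V1, k_candidates = 1, restarts = 2, seed = 21)
  expect_lt(tab1$divergence, 1e-4)

  tab_single <- pick_rank(V, k_candidates = 2, restarts = 1, seed = 23)
  expect_true(is.na(tab_single$stability))
})

test_that("exposures_by_group gives textbook means and standard errors", {
  E <- rbind(S1 = c(100, 100, 100, 90, 100, 110, 50),
             S2 = c(10, 20, 30, 5, 10, 15, 7))
  colnames(E) <- paste0("s", 1:7)
  groups <- tibble::tibble(sample = paste0("s", 1:7),
                           group = c("a", "a", "a", "b", "b", "b", "c"))
  out <- exposures_by_group(E, groups)
  a1 <- out[out$group == "a" & out$component == "S1", ]
  expect_equal(a1$mean_exposure, 100)
  expect_equal(a1$sem, 0)
  b1 <- out[out$group == "b" & out$component == "S1", ]
  expect_equal(b1$mean_exposure, 100)
  expect_equal(b1$sem, 5.7735, tolerance = 1e-4)
  expect_true(is.na(out$sem[out$group == "c"][1]))

  expect_error(exposures_by_group(E, groups[1:3, ]), "without a group")
})

test_that("cosine similarity to references matches a direct dot-product oracle", {
  refs <- tibble::tibble(channel = sbs_channels()$channel,
                         ref1 = platinum_signature()$channel_probs,
                         ref2 = background_signature()$channel_probs)
  S <- cbind(A = unname(platinum_signature()$channel_probs))
  rownames(S) <- sbs_channels()$channel
  out <- cosine_to_reference(S, refs)
  expect_equal(out$cosine[out$reference == "ref1"], 1, tolerance = 1e-12)

  # disjoint supports
  d1 <- rep(0, 96); d1[1:10] <- 0.1
  d2 <- rep(0, 96); d2[11:20] <- 0.1
  S2 <- cbind(A = d1); rownames(S2) <- sbs_channels()$channel
  refs2 <- tibble::tibble(channel = sbs_channels()$channel, ref = d2)
  expect_equal(cosine_to_reference(S2, refs2)$cosine, 0)

  # random vectors against an independent implementation
  withr::with_seed(25, {
    for (i in 1:5) {
      a <- runif(96); b <- runif(96)
      oracle <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
      Sa <- cbind(X = a); rownames(Sa) <- sbs_channels()$channel
      got <- cosine_to_reference(
        Sa, tibble::tibble(channel = sbs_channels()$channel, r = b))$cosine
      expect_equal(got, oracle, tolerance = 1e-12)
    }
  })

  bad <- refs; bad$channel[5] <- "A[C>X]A"
  expect_error(cosine_to_reference(S, bad), "A\\[C>X\\]A")
})

test_that("PCA of normalized spectra separates groups and reconstructs exactly", {
  # identical spectra: all coordinates zero
  s <- background_signature()$channel_probs
  V_same <- outer(unname(s), rep(1000, 3))
  dimnames(V_same) <- list(sbs_channels()$channel, paste0("s", 1:3))
  p_same <- pca_spectra(V_same)
  expect_true(all(abs(as.matrix(p_same$scores[, -1])) < 1e-9))
  expect_true(all(p_same$explained == 0))

  # two well-separated groups: PC1 ranges do not overlap
  V <- mixture_matrix(c(rep(0, 4), rep(0.8, 4)), rep(2000, 8),
                      platinum_signature()$channel_probs,
                      background_signature()$channel_probs, seed = 27)
  p <- pca_spectra(V)
  pc1 <- p$scores$PC1
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) || min(pc1[1:4]) > max(pc1[5:8]))

  # orthogonal reconstruction identity
  Vn <- sweep(V, 2, colSums(V), "/")
  centred <- t(Vn) - matrix(rowMeans(Vn), ncol(V), 96, byrow = TRUE)
  recon <- as.matrix(p$scores[, -1]) %*% t(p$rotation)
  expect_lt(max(abs(recon - centred)), 1e-9)

  expect_error(pca_spectra(V[, 1, drop = FALSE]), "at least 2")
})
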