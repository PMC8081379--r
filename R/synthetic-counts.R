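#' Emit noisy per-site allele counts for all clones
#'
#' Replaces read alignment: for every planted site and for a configurable
#' number of clean "noise" sites, each sample receives a Poisson coverage
#' around the design mean.  The mutated clone's alternate reads at a
#' heterozygous SNV are Binomial(coverage, vaf); every other read is the
#' reference base except for miscalls at `seq_error_rate`, distributed
#' uniformly over the three non-reference bases.  Indel sites carry
#' indel-supporting read counts analogously, and indel-supporting noise
#' reads arise at the same error rate.
#'
#' @param ref A [make_reference()] genome.
#' @param truth A [plant_mutations()] table (possibly empty).
#' @param design The [experiment_design()]; controls the coverage, error
#'   rate, VAF and the default noise-site count
#'   (`noise_site_factor * nrow(truth)`).
#' @param noise_sites Number of clean sites to emit; overrides the design
#'   default.
#' @return A tibble of class `site_counts` in long form: `contig`, `pos`
#'   (1-based), `ref_base`, `sample`, `cov`, `A`, `C`, `G`, `T`,
#'   `ins_support`, `del_support`.  One row per site per sample, sorted by
#'   site then sample.
#' @export
emit_counts <- function(ref, truth, design, noise_sites = NULL) {
  stopifnot(inherits(ref, "ref_genome"), inherits(design, "experiment_design"))
  samples <- design_samples(design)$sample
  if (is.null(noise_sites)) {
    noise_sites <- round(design$noise_site_factor * nrow(truth))
  }
  if (nrow(truth) == 0 && noise_sites == 0) {
    out <- tibble(contig = character(), pos = integer(),
                  ref_base = character(), sample = character(),
                  cov = integer(), A = integer(), C = integer(),
                  G = integer(), T = integer(), ins_support = integer(),
                  del_support = integer())
    class(out) <- c("site_counts", class(tibble()))
    return(out)
  }

  withr::with_seed(sub_seed(design$seed, "counts"), {
    lens <- nchar(ref$contigs)
    interior <- pmax(lens - 2L, 0L)
    offsets <- c(0, cumsum(as.numeric(interior)))
    total_interior <- offsets[length(offsets)]

    site_truth <- if (nrow(truth) > 0) {
      tibble(
        contig = truth$contig, pos = truth$pos,
        ref_base = substr(truth$ref, 1, 1),
        mut_sample = truth$clone, mut_type = truth$type,
        alt_base = ifelse(truth$type == "SNV", truth$alt, NA_character_)
      )
    } else {
      tibble(contig = character(), pos = integer(), ref_base = character(),
             mut_sample = character(), mut_type = character(),
             alt_base = character())
    }

    site_noise <- NULL
    if (noise_sites > 0) {
      if (total_interior < noise_sites) {
        abort("genome too small for the requested number of noise sites.")
      }
      used <- paste(site_truth$contig, site_truth$pos)
      picked <- character(0)
      keys <- integer(0)
      for (attempt in 1:20) {
        need <- noise_sites - length(keys)
        if (need <= 0) break
        g <- sample.int(total_interior, need, replace = TRUE)
        ci <- findInterval(g - 1, offsets, rightmost.closed = FALSE)
        pos <- as.integer(g - offsets[ci] + 1L)  # interior index 2..L-1
        k <- paste(names(lens)[ci], pos)
        fresh <- !(k %in% used) & !(k %in% picked) & !duplicated(k)
        keys <- c(keys, g[fresh])
        picked <- c(picked, k[fresh])
      }
      if (length(keys) < noise_sites) {
        abort("could not draw enough distinct noise sites.")
      }
      ci <- findInterval(keys - 1, offsets, rightmost.closed = FALSE)
      pos <- as.integer(keys - offsets[ci] + 1L)
      cn <- names(lens)[ci]
      site_noise <- tibble(
        contig = cn, pos = pos,
        ref_base = ref_base_at(ref, cn, pos),
        mut_sample = NA_character_, mut_type = NA_character_,
        alt_base = NA_character_
      )
    }

    sites <- bind_rows(site_truth, site_noise) |>
      arrange(.data$contig, .data$pos)

    ns <- nrow(sites)
    nsamp <- length(samples)
    N <- ns * nsamp
    site_i <- rep(seq_len(ns), each = nsamp)
    samp <- rep(samples, times = ns)

    cov <- rpois(N, design$coverage_mean)
    is_mut <- !is.na(sites$mut_sample[site_i]) &
      sites$mut_sample[site_i] == samp
    mut_type <- sites$mut_type[site_i]

    alt_n <- integer(N)
    snv_mut <- is_mut & mut_type == "SNV"
    alt_n[snv_mut] <- rbinom(sum(snv_mut), cov[snv_mut], design$vaf)

    ins_n <- integer(N)
    del_n <- integer(N)
    ins_mut <- is_mut & mut_type == "INS"
    del_mut <- is_mut & mut_type == "DEL"
    ins_n[ins_mut] <- rbinom(sum(ins_mut), cov[ins_mut], design$vaf)
    del_n[del_mut] <- rbinom(sum(del_mut), cov[del_mut], design$vaf)

    err <- design$seq_error_rate
    err_n <- rbinom(N, cov - alt_n, err)
    e1 <- rbinom(N, err_n, 1 / 3)
    e2 <- rbinom(N, err_n - e1, 1 / 2)
    e3 <- err_n - e1 - e2
    e_mat <- cbind(e1, e2, e3)

    ins_err <- rbinom(N, cov, err)
    del_err <- rbinom(N, cov, err)
    ins_support <- pmin(ins_n + ins_err, cov)
    del_support <- pmin(del_n + del_err, cov)

    ref_code <- match(sites$ref_base[site_i], BASES)
    alt_code <- match(sites$alt_base[site_i], BASES)
    ref_n <- cov - alt_n - err_n

    base_counts <- matrix(0L, N, 4, dimnames = list(NULL, BASES))
    for (b in 1:4) {
      cnt <- integer(N)
      cnt[ref_code == b] <- ref_n[ref_code == b]
      hit_alt <- !is.na(alt_code) & alt_code == b & snv_mut
      cnt[hit_alt] <- cnt[hit_alt] + alt_n[hit_alt]
      nonref <- ref_code != b
      slot <- b - as.integer(b > ref_code)   # rank of b among non-ref bases
      pick <- which(nonref)
      cnt[pick] <- cnt[pick] + e_mat[cbind(pick, slot[pick])]
      base_counts[, b] <- cnt
    }

    out <- tibble(
      contig = sites$contig[site_i], pos = sites$pos[site_i],
      ref_base = sites$ref_base[site_i], sample = samp,
      cov = as.integer(cov),
      A = base_counts[, 1], C = base_counts[, 2],
      G = base_counts[, 3], T = base_counts[, 4],
      ins_support = as.integer(ins_support),
      del_support = as.integer(del_support)
    )
    class(out) <- c("site_counts", class(tibble()))
    attr(out, "samples") <- samples
    out
  })
}
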