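kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

nmf_single <- function(V, k, max_iter, tol, seed, track = FALSE) {
  eps <- 1e-12
  m <- nrow(V)
  n <- ncol(V)
  withr::with_seed(seed, {
    W <- matrix(runif(m * k), m, k)
    H <- matrix(runif(k * n) * mean(V) * m / k, k, n)
  })
  WH <- W %*% H
  div <- kl_divergence(V, pmax(WH, eps))
  trace <- if (track) div else NULL
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # multiplicative updates for generalized Kullback-Leibler divergence
    H <- H * (t(W) %*% (V / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) /
      matrix(pmax(rowSums(H), eps), m, k, byrow = TRUE)
    WH <- W %*% H
    new_div <- kl_divergence(V, pmax(WH, eps))
    if (track) trace <- c(trace, new_div)
    if (abs(div - new_div) <= tol * max(abs(div), 1)) {
      div <- new_div
      converged <- TRUE
      break
    }
    div <- new_div
  }
  list(W = W, H = H, divergence = div, iterations = it,
       converged = converged, trace = trace)
}

#' De novo NMF decomposition of mutation spectra
#'
#' Factorizes a non-negative 96 x n channel-by-sample matrix `V` into `k`
#' signatures and exposures, `V ~ S %*% E`, by minimizing the generalized
#' Kullback-Leibler divergence with the classical multiplicative updates.
#' Several random restarts are run from a seeded stream and the fit with
#' the lowest final divergence is returned.  Signatures are
#' column-normalized to probability vectors with the scale folded into the
#' exposures, so exposures are in mutation-count units; components are
#' ordered by decreasing total exposure.
#'
#' @param V A `spectrum96` tibble (long form) or a 96 x n non-negative
#'   matrix with channel rownames.
#' @param k Number of components (`1 <= k <= min(96, n)`).
#' @param restarts Number of random initializations.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative divergence-change stopping tolerance.
#' @param seed Master seed; restart `r` uses the `"nmf<r>"` sub-stream.
#' @param track_divergence Keep the per-iteration divergence trace of the
#'   winning restart (for monotonicity checks).
#' @return An object of class `mut_nmf`: `signatures` (96 x k, columns sum
#'   to 1), `exposures` (k x n), `divergence`, `iterations`, `converged`,
#'   plus the call parameters.  Use [tidy()] / [glance()] to extract tidy
#'   summaries.
#' @export
nmf_fit <- function(V, k, restarts = 50, max_iter = 2000, tol = 1e-8,
                    seed = 1, track_divergence = FALSE) {
  if (is_tibble(V) || is.data.frame(V)) V <- spectrum_matrix(V)
  V <- as.matrix(V)
  if (any(V < 0) || any(!is.finite(V))) abort("`V` must be non-negative and finite.")
  zero_col <- colSums(V) == 0
  if (any(zero_col)) {
    abort(paste0("all-zero sample column(s): ",
                 paste(colnames(V)[zero_col], collapse = ", ")))
  }
  if (k < 1 || k > min(nrow(V), ncol(V))) {
    abort("`k` must satisfy 1 <= k <= min(96, n_samples).")
  }
  runs <- lapply(seq_len(restarts), function(r) {
    nmf_single(V, k, max_iter, tol, sub_seed(seed, paste0("nmf", r)),
               track = track_divergence)
  })
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "divergence"))]]

  s <- colSums(best$W)
  S <- sweep(best$W, 2, s, "/")
  E <- best$H * s
  ord <- order(rowSums(E), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  E <- E[ord, , drop = FALSE]
  comp <- paste0("S", seq_len(k))
  dimnames(S) <- list(rownames(V), comp)
  dimnames(E) <- list(comp, colnames(V))
  structure(
    list(signatures = S, exposures = E, divergence = best$divergence,
         iterations = best$iterations, converged = best$converged,
         k = k, restarts = restarts, seed = seed,
         restart_divergences = vapply(runs, `[[`, numeric(1), "divergence"),
         divergence_trace = best$trace),
    class = "mut_nmf"
  )
}

#' @export
print.mut_nmf <- function(x, ...) {
  cat("<mut_nmf> k = ", x$k, ", ", ncol(x$exposures), " samples, ",
      "divergence = ", signif(x$divergence, 6),
      " (", x$restarts, " restarts, ",
      if (x$converged) "converged" else "max_iter reached", ")\n", sep = "")
  invisible(x)
}

#' @rdname nmf_fit
#' @param x A `mut_nmf` object.
#' @param matrix Which factor to tidy: `"signatures"` (channel
#'   probabilities) or `"exposures"` (mutation counts per sample).
#' @param ... Unused.
#' @export
tidy.mut_nmf <- function(x, matrix = c("signatures", "exposures"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "signatures") {
    as_tibble(x$signatures, rownames = "channel") |>
      pivot_longer(-"channel", names_to = "component",
                   values_to = "probability") |>
      mutate(channel = factor(.data$channel, levels = channel_levels())) |>
      arrange(.data$component, .data$channel)
  } else {
    as_tibble(x$exposures, rownames = "component") |>
      pivot_longer(-"component", names_to = "sample",
                   values_to = "exposure")
  }
}

#' @rdname nmf_fit
#' @export
glance.mut_nmf <- function(x, ...) {
  tibble(k = x$k, divergence = x$divergence, iterations = x$iterations,
         converged = x$converged, restarts = x$restarts)
}

match_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (length(rest) == 0) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(k))
  out
}

#' Match estimated components to reference components
#'
#' Finds the one-to-one assignment of columns of `A` to columns of `B`
#' maximizing the total cosine similarity (exhaustive over permutations for
#' up to 6 components, greedy beyond).
#'
#' @param A,B Matrices with the same number of rows; `ncol(A) <= ncol(B)`.
#' @return A tibble with `component_a`, `component_b`, `cosine`.
#' @export
match_components <- function(A, B) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  k <- ncol(A)
  stopifnot(k <= ncol(B))
  cm <- cosine_matrix(A, B)
  if (k <= 6 && ncol(B) <= 6 && k == ncol(B)) {
    perms <- match_permutations(k)
    tot <- vapply(perms, function(p) sum(cm[cbind(seq_len(k), p)]), numeric(1))
    p <- perms[[which.max(tot)]]
  } else {
    p <- integer(k)
    taken <- logical(ncol(B))
    for (i in order(apply(cm, 1, max), decreasing = TRUE)) {
      j <- order(cm[i, ], decreasing = TRUE)
      j <- j[!taken[j]][1]
      p[i] <- j
      taken[j] <- TRUE
    }
  }
  tibble(
    component_a = colnames(A) %||% paste0("A", seq_len(k)),
    component_b = (colnames(B) %||% paste0("B", seq_len(ncol(B))))[p],
    cosine = cm[cbind(seq_len(k), p)]
  )
}

#' Rank survey for NMF
#'
#' For each candidate rank, reports the best divergence across restarts and
#' the stability of the recovered signatures: the mean cosine similarity of
#' matched components over all pairs of restarts.  No rank is selected
#' automatically; the table is for inspection.
#'
#' @inheritParams nmf_fit
#' @param k_candidates Integer vector of ranks to try.
#' @return A tibble with `k`, `divergence` and `stability` (`NA` with a
#'   single restart).
#' @export
pick_rank <- function(V, k_candidates, restarts = 10, max_iter = 2000,
                      tol = 1e-8, seed = 1) {
  if (length(k_candidates) == 0) abort("`k_candidates` must be non-empty.")
  if (is_tibble(V) || is.data.frame(V)) V <- spectrum_matrix(V)
  rows <- lapply(k_candidates, function(k) {
    runs <- lapply(seq_len(restarts), function(r) {
      nmf_single(V, k, max_iter, tol, sub_seed(seed, paste0("nmf", r)))
    })
    divs <- vapply(runs, `[[`, numeric(1), "divergence")
    stability <- NA_real_
    if (restarts > 1) {
      sigs <- lapply(runs, function(z) sweep(z$W, 2, pmax(colSums(z$W), 1e-12), "/"))
      pair_cos <- c()
      for (i in seq_len(restarts - 1)) {
        for (j in (i + 1):restarts) {
          pair_cos <- c(pair_cos, mean(match_components(sigs[[i]], sigs[[j]])$cosine))
        }
      }
      stability <- mean(pair_cos)
    }
    tibble(k = k, divergence = min(divs), stability = stability)
  })
  bind_rows(rows)
}

#' Mean and standard error of exposures per treatment group
#'
#' @param fit A [nmf_fit()] object (or a k x n exposure matrix).
#' @param groups Tibble mapping `sample` to `group`; every fitted sample
#'   must belong to exactly one group.
#' @return A tibble with `group`, `component`, `n`, `mean_exposure` and
#'   `sem` (`NA` for groups of size 1).
#' @export
exposures_by_group <- function(fit, groups) {
  E <- if (inherits(fit, "mut_nmf")) fit$exposures else as.matrix(fit)
  groups <- as_tibble(groups)
  stopifnot(all(c("sample", "group") %in% names(groups)))
  if (anyDuplicated(groups$sample)) {
    abort("every sample must be assigned to exactly one group.")
  }
  missing <- setdiff(colnames(E), groups$sample)
  if (length(missing) > 0) {
    abort(paste0("samples without a group: ", paste(missing, collapse = ", ")))
  }
  as_tibble(E, rownames = "component") |>
    pivot_longer(-"component", names_to = "sample", values_to = "exposure") |>
    inner_join(groups, by = "sample") |>
    group_by(.data$group, .data$component) |>
    summarise(
      n = n(),
      mean_exposure = mean(.data$exposure),
      sem = ifelse(n() > 1, sd(.data$exposure) / sqrt(n()), NA_real_),
      .groups = "drop"
    )
}

#' Cosine similarity of fitted signatures to a reference catalogue
#'
#' @param fit A `mut_nmf` object or a 96 x k signature matrix with channel
#'   rownames.
#' @param refs Reference signatures: a tibble with a `channel` column (96
#'   labels in the frozen order) and one numeric column per reference, as
#'   read by [read_signatures_tsv()].
#' @return A tibble with `component`, `reference` and `cosine` in `[0, 1]`.
#' @export
cosine_to_reference <- function(fit, refs) {
  S <- if (inherits(fit, "mut_nmf")) fit$signatures else as.matrix(fit)
  refs <- as_tibble(refs)
  if (!"channel" %in% names(refs)) abort("`refs` must have a `channel` column.")
  mism <- which(refs$channel != channel_levels())
  if (length(refs$channel) != 96 || length(mism) > 0) {
    bad <- if (length(refs$channel) != 96) "wrong channel count" else
      paste0("first mismatching label: ", refs$channel[mism[1]])
    abort(paste0("`refs` does not follow the frozen 96-channel order (",
                 bad, ")."))
  }
  R <- as.matrix(refs[, setdiff(names(refs), "channel"), drop = FALSE])
  cm <- cosine_matrix(S, R)
  as_tibble(cm, rownames = "component") |>
    pivot_longer(-"component", names_to = "reference", values_to = "cosine")
}
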