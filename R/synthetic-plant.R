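#' Plant unique mutations from a two-signature mixture
#'
#' For every descendant clone, draws a Poisson SNV count, assigns each SNV
#' to the direct or background signature by the group's mixture weight,
#' draws a channel from that signature, and places it uniformly among
#' genomic positions whose pyrimidine-centred trinucleotide context matches
#' the channel (either strand).  In-gene direct-component SNVs land with
#' probability `ts_bias` on the transcribed strand (i.e. the pyrimidine of
#' the mutated pair sits on the template strand), emulating
#' transcription-coupled repair of purine-purine platinum adducts.  Short
#' 1-bp indels are planted at each signature's `indel_rate` per SNV.  No two
#' clones ever share a site.
#'
#' @param ref A [make_reference()] genome.
#' @param design An [experiment_design()]; control clones receive no
#'   mutations.
#' @param direct,background [signature_spec()]s for the two components.
#' @param max_retries Bounded retries used to resolve site collisions.
#' @return A tibble of class `planted_truth` with columns `clone`, `contig`,
#'   `pos` (1-based), `ref`, `alt`, `type` (`SNV`/`INS`/`DEL`), `component`,
#'   `channel`, `pyr_strand`, `in_gene`.  Indel alleles are anchored (the
#'   reference base before the event is included).
#' @export
#' @examples
#' ref <- make_reference(20000, gene_fraction = 0.3, seed = 1)
#' design <- experiment_design(
#'   groups = tibble::tibble(drug = "cisplatin", dose = "IC50",
#'                           mean_snvs = 50, direct_weight = 0.6),
#'   clones_per_group = 2, n_control_clones = 0, seed = 1
#' )
#' truth <- plant_mutations(ref, design)
plant_mutations <- function(ref, design,
                            direct = platinum_signature(),
                            background = background_signature(),
                            max_retries = 20) {
  stopifnot(inherits(ref, "ref_genome"), inherits(design, "experiment_design"),
            inherits(direct, "signature_spec"),
            inherits(background, "signature_spec"))
  idx <- context_index(ref)
  samples <- design_samples(design) |> filter(.data$role != "control")
  chan_ctx <- channel_ctx32()
  ch_tab <- sbs_channels()

  empty_truth <- function() {
    structure(
      tibble(clone = character(), contig = character(), pos = integer(),
             ref = character(), alt = character(), type = character(),
             component = character(), channel = character(),
             pyr_strand = character(), in_gene = logical()),
      class = c("planted_truth", "tbl_df", "tbl", "data.frame")
    )
  }

  withr::with_seed(sub_seed(design$seed, "planting"), {
    # --- draw SNV requests per clone ------------------------------------
    reqs <- vector("list", nrow(samples))
    for (si in seq_len(nrow(samples))) {
      grp <- design$groups[design$groups$group == samples$group[si], ]
      n <- rpois(1, grp$mean_snvs)
      nd <- rbinom(1, n, grp$direct_weight)
      parts <- list()
      if (nd > 0) {
        parts$d <- tibble(
          clone = samples$sample[si], component = "direct",
          chan = sample.int(96, nd, replace = TRUE,
                            prob = direct$channel_probs)
        )
      }
      if (n - nd > 0) {
        parts$b <- tibble(
          clone = samples$sample[si], component = "background",
          chan = sample.int(96, n - nd, replace = TRUE,
                            prob = background$channel_probs)
        )
      }
      reqs[[si]] <- bind_rows(parts)
    }
    req <- bind_rows(reqs)

    # --- site pools by context and strand category ----------------------
    cat_vec <- ifelse(!idx$in_gene, "inter",
                      ifelse(idx$pyr_strand != idx$gene_strand,
                             "gene_ts", "gene_uts"))
    pool_any <- split(seq_len(nrow(idx)), idx$ctx32)
    pool_cat <- split(seq_len(nrow(idx)), paste(idx$ctx32, cat_vec))

    n_snv <- nrow(req)
    assign_row <- integer(0)
    if (n_snv > 0) {
      req$ctx <- chan_ctx[req$chan]
      # per-context genic fraction for direct-site categories
      ctx_any_n <- lengths(pool_any)[as.character(req$ctx)]
      gts <- lengths(pool_cat)[paste(req$ctx, "gene_ts")]
      guts <- lengths(pool_cat)[paste(req$ctx, "gene_uts")]
      ctx_gene_n <- ifelse(is.na(gts), 0, gts) + ifelse(is.na(guts), 0, guts)
      missing_ctx <- is.na(ctx_any_n) | ctx_any_n == 0
      if (any(missing_ctx)) {
        bad <- ch_tab$channel[req$chan[which(missing_ctx)[1]]]
        abort(paste0("channel ", bad, ": no position in the reference ",
                     "matches its trinucleotide context."))
      }
      is_dir <- req$component == "direct"
      in_gene_draw <- runif(n_snv) < (ctx_gene_n / ctx_any_n)
      ts_draw <- runif(n_snv) < direct$ts_bias
      req$category <- "any"
      req$category[is_dir & in_gene_draw & ts_draw] <- "gene_ts"
      req$category[is_dir & in_gene_draw & !ts_draw] <- "gene_uts"
      req$category[is_dir & !in_gene_draw] <- "inter"

      pool_of <- function(ctx, category) {
        if (category == "any") return(pool_any[[as.character(ctx)]])
        p <- pool_cat[[paste(ctx, category)]]
        if (is.null(p) || length(p) == 0) p <- pool_any[[as.character(ctx)]]
        p
      }

      assign_row <- rep(NA_integer_, n_snv)
      todo <- seq_len(n_snv)
      key <- paste(req$ctx, req$category)
      for (attempt in seq_len(max_retries)) {
        for (rows in split(todo, key[todo])) {
          pool <- pool_of(req$ctx[rows[1]], req$category[rows[1]])
          assign_row[rows] <- pool[sample.int(length(pool), length(rows),
                                              replace = TRUE)]
        }
        dup <- duplicated(assign_row)
        todo <- which(dup)
        if (length(todo) == 0) break
      }
      if (length(todo) > 0) {
        abort("could not place all mutations on distinct sites; the genome is too small for the requested burden.")
      }
    }

    snv <- empty_truth()
    if (n_snv > 0) {
      rows <- idx[assign_row, ]
      plus <- rows$pyr_strand == "+"
      refb <- ifelse(plus, ch_tab$ref[req$chan], comp_base(ch_tab$ref[req$chan]))
      altb <- ifelse(plus, ch_tab$alt[req$chan], comp_base(ch_tab$alt[req$chan]))
      snv <- tibble(
        clone = req$clone, contig = rows$contig, pos = rows$pos,
        ref = refb, alt = altb, type = "SNV", component = req$component,
        channel = ch_tab$channel[req$chan],
        pyr_strand = rows$pyr_strand, in_gene = rows$in_gene
      )
    }

    # --- 1-bp indels at indel_rate per SNV ------------------------------
    comp_counts <- if (nrow(req) > 0) {
      count(req, .data$clone, .data$component)
    } else {
      tibble(clone = character(), component = character(), n = integer())
    }
    ind_list <- list()
    used <- assign_row
    if (nrow(comp_counts) > 0) {
      for (ri in seq_len(nrow(comp_counts))) {
        sig <- if (comp_counts$component[ri] == "direct") direct else background
        n_ind <- rpois(1, sig$indel_rate * comp_counts$n[ri])
        if (n_ind == 0) next
        rows_i <- rep(NA_integer_, n_ind)
        todo <- seq_len(n_ind)
        for (attempt in seq_len(max_retries)) {
          rows_i[todo] <- sample.int(nrow(idx), length(todo), replace = TRUE)
          bad <- duplicated(c(used, rows_i))[length(used) + seq_len(n_ind)]
          todo <- which(bad)
          if (length(todo) == 0) break
        }
        if (length(todo) > 0) abort("could not place indels on distinct sites.")
        used <- c(used, rows_i)
        at <- idx[rows_i, ]
        is_del <- runif(n_ind) < design$deletion_fraction
        anchor <- ref_base_at(ref, at$contig, at$pos)
        next_base <- ref_base_at(ref, at$contig, at$pos + 1L)
        ins_base <- sample(BASES, n_ind, replace = TRUE)
        ind_list[[length(ind_list) + 1L]] <- tibble(
          clone = comp_counts$clone[ri], contig = at$contig, pos = at$pos,
          ref = ifelse(is_del, paste0(anchor, next_base), anchor),
          alt = ifelse(is_del, anchor, paste0(anchor, ins_base)),
          type = ifelse(is_del, "DEL", "INS"),
          component = comp_counts$component[ri],
          channel = ifelse(is_del, "DEL:1bp", "INS:1bp"),
          pyr_strand = NA_character_, in_gene = at$in_gene
        )
      }
    }
    out <- bind_rows(snv, bind_rows(ind_list)) |>
      arrange(.data$clone, .data$contig, .data$pos)
    class(out) <- c("planted_truth", class(tibble()))
    out
  })
}
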