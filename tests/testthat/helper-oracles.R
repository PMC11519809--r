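# Independent scalar-loop oracles: literal transcriptions of the scoring and
# selection rules, deliberately unvectorized, used to cross-check the
# package's matrix implementations.

oracle_score_one <- function(red, white, fold = 5, tau = 1) {
  if (white == 0 && red >= tau) return(2L)
  if (white > 0 && red / white >= fold) return(1L)
  0L
}

oracle_score_matrix <- function(red_mat, white_mat, fold = 5, tau = 1) {
  out <- matrix(0L, nrow(red_mat), ncol(red_mat),
                dimnames = dimnames(red_mat))
  for (g in seq_len(nrow(red_mat))) {
    for (p in seq_len(ncol(red_mat))) {
      out[g, p] <- oracle_score_one(red_mat[g, p], white_mat[g, p],
                                    fold, tau)
    }
  }
  out
}

# literal set-builder for candidate selection: base rule, discard, rescue
oracle_select <- function(ranked_ids, scores, folds, rule, min_agg,
                          discard, k, f_high) {
  base <- character()
  for (g in ranked_ids) {
    ok <- if (rule == "all_pairs_positive") {
      all(scores[g, ] >= 1)
    } else {
      sum(scores[g, ]) >= min_agg
    }
    if (ok && !(g %in% discard)) base <- c(base, g)
  }
  rescued <- character()
  for (g in ranked_ids) {
    n_q <- 0L
    for (p in seq_len(ncol(scores))) {
      f <- folds[g, p]
      if (scores[g, p] == 2L || (!is.na(f) && f >= f_high)) n_q <- n_q + 1L
    }
    if (n_q >= k && !(g %in% base) && !(g %in% discard)) {
      rescued <- c(rescued, g)
    }
  }
  c(base, rescued)
}

# small abundance fixture: n_genes x (2 * n_pairs) matrix plus matching sheet
make_paired_fixture <- function(n_genes, n_pairs, abundances_red,
                                abundances_white) {
  sheet <- tidyr::expand_grid(method = "manual",
                              replicate = seq_len(n_pairs),
                              color = c("red", "white"))
  sheet$sample_id <- sprintf("%s_%d_%s", sheet$method, sheet$replicate,
                             sheet$color)
  sheet <- sheet[, c("sample_id", "color", "method", "replicate")]
  gene_ids <- if (is.null(rownames(abundances_red))) {
    sprintf("g%03d", seq_len(n_genes))
  } else {
    rownames(abundances_red)
  }
  ab <- matrix(0, n_genes, 2 * n_pairs,
               dimnames = list(gene_ids, sheet$sample_id))
  ab[, grepl("_red$", colnames(ab))] <- abundances_red
  ab[, grepl("_white$", colnames(ab))] <- abundances_white
  list(abundance = ab, sheet = sheet)
}

noise_free_config <- function(seed = 11L, ...) {
  simulation_config(
    seed = seed,
    dispersion_by_method = c(laser = 0.01, manual = 0.01),
    dropout_prob_by_method = c(laser = 0, manual = 0),
    contamination_by_method = c(laser = 0, manual = 0),
    ...
  )
}

# stage table for a single gene following the full marker trajectory, which
# individual tests then perturb
marker_stage_table <- function(gene_id = "g1", n_elong = 3,
                               on_value = 10) {
  grid <- tidyr::expand_grid(
    gene_id = gene_id,
    dplyr::bind_rows(
      tibble::tibble(stage = "gastrulation", timepoint = 1L),
      tibble::tibble(stage = "initiation", timepoint = 1L),
      tibble::tibble(stage = "elongation", timepoint = seq_len(n_elong))
    ),
    region = msz_regions()
  )
  grid$value <- ifelse(grid$stage != "gastrulation" &
                         grid$region == "anterior_PS", on_value, 0)
  grid
}
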