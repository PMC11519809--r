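#' Aggregate pair scores and rank genes
#'
#' The aggregate score of a gene is the sum of its per-pair scores (0..2 per
#' pair, so at most `2 * n_pairs`). Genes are ranked by aggregate score
#' descending; ties are broken deterministically by number of score-2 pairs
#' (descending), then mean log-fold `log(red+1) - log(white+1)` across pairs
#' (descending), then gene id (ascending).
#'
#' @param pair_scores an `msz_pair_scores` from [score_all_pairs()].
#' @return a tibble with columns gene_id, aggregate_score, n_pairs_score2,
#'   n_pairs_score1, mean_log_fold, rank; sorted by rank (1 = best).
#' @export
aggregate_and_rank <- function(pair_scores) {
  stopifnot(inherits(pair_scores, "msz_pair_scores"))
  s <- pair_scores$scores
  ranking <- tibble::tibble(
    gene_id = rownames(s),
    aggregate_score = as.integer(rowSums(s)),
    n_pairs_score2 = as.integer(rowSums(s == 2L)),
    n_pairs_score1 = as.integer(rowSums(s == 1L)),
    mean_log_fold = rowMeans(pair_scores$log_folds)
  )
  ord <- order(-ranking$aggregate_score, -ranking$n_pairs_score2,
               -ranking$mean_log_fold, ranking$gene_id, method = "radix")
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  ranking
}

#' Parameters of candidate selection
#'
#' @param consistency_rule how "consistently red-enriched" is operationalized:
#'   `"all_pairs_positive"` (score >= 1 in every pair, the default) or
#'   `"min_aggregate"` (aggregate score at least `min_aggregate_score`).
#' @param min_aggregate_score aggregate-score floor for the
#'   `min_aggregate` rule.
#' @param discard_list gene ids known a priori to be non-specific; always
#'   excluded, even from rescue.
#' @param rescue_min_pairs minimum number of qualifying pairs (`k`) for the
#'   rescue of a low-ranking gene showing very dissimilar red/white levels in
#'   at least some pairs.
#' @param rescue_fold fold-change (`F_high`) that makes a pair qualify for
#'   rescue when its score is not already 2.
#' @return an object of class `msz_selection_params`.
#' @export
selection_params <- function(consistency_rule = c("all_pairs_positive",
                                                  "min_aggregate"),
                             min_aggregate_score = 6L,
                             discard_list = character(),
                             rescue_min_pairs = 2L,
                             rescue_fold = 25) {
  consistency_rule <- match.arg(consistency_rule)
  check_scalar_number(min_aggregate_score, "min_aggregate_score", lower = 0)
  check_scalar_number(rescue_min_pairs, "rescue_min_pairs", lower = 0)
  check_scalar_number(rescue_fold, "rescue_fold", lower = 1)
  structure(list(consistency_rule = consistency_rule,
                 min_aggregate_score = as.integer(min_aggregate_score),
                 discard_list = as.character(discard_list),
                 rescue_min_pairs = as.integer(rescue_min_pairs),
                 rescue_fold = rescue_fold),
            class = "msz_selection_params")
}

#' Select candidate genes from the ranking
#'
#' The base set holds genes consistently more expressed in the red (MSZ)
#' sample of every pair, per the configured consistency rule, minus the
#' discard list of genes known to be non-specific. Low-ranking genes are
#' rescued when at least `rescue_min_pairs` pairs show very dissimilar
#' levels (pair score 2, or reported fold >= `rescue_fold`); rescued genes
#' are appended after the base set, both in rank order, and the discard list
#' also excludes them.
#'
#' @param ranking tibble from [aggregate_and_rank()].
#' @param pair_scores the matching `msz_pair_scores`.
#' @param sel an `msz_selection_params`.
#' @return character vector of selected gene ids, rank-ordered (base set
#'   first, then rescued genes).
#' @export
select_candidates <- function(ranking, pair_scores,
                              sel = selection_params()) {
  stopifnot(inherits(pair_scores, "msz_pair_scores"),
            inherits(sel, "msz_selection_params"))
  if (sel$rescue_min_pairs > ncol(pair_scores$scores)) {
    stop_field("rescue_min_pairs", "exceeds the number of pairs")
  }
  if (sel$rescue_fold < pair_scores$params$fold_threshold) {
    stop_field("rescue_fold", "must be >= the scoring fold_threshold")
  }
  s <- pair_scores$scores
  base_ok <- if (sel$consistency_rule == "all_pairs_positive") {
    rowSums(s >= 1L) == ncol(s)
  } else {
    rowSums(s) >= sel$min_aggregate_score
  }
  folds <- pair_scores$fold_changes
  qualifying <- s == 2L | (!is.na(folds) & folds >= sel$rescue_fold)
  rescue_ok <- rowSums(qualifying) >= sel$rescue_min_pairs

  ranked_ids <- ranking$gene_id
  base <- ranked_ids[base_ok[ranked_ids]]
  base <- setdiff(base, sel$discard_list)
  rescued <- ranked_ids[rescue_ok[ranked_ids]]
  rescued <- setdiff(rescued, c(base, sel$discard_list))
  c(base, rescued)
}
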