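#' Parameters of the pairwise red/white enrichment score
#'
#' @param fold_threshold minimum red/white fold for a score of 1 (must be
#'   > 1; default 5).
#' @param tau minimum normalized red abundance for a "significant" detection,
#'   required for a score of 2 when the white partner is zero. Units follow
#'   `normalization` (CPM by default).
#' @param pseudocount epsilon added to the white abundance when *reporting*
#'   fold-changes; never used in score decisions. With `pseudocount = 0` the
#'   fold-change at white = 0 is reported as undefined (`NA`), not infinity.
#' @param normalization `"cpm"` (counts per million, the default) or
#'   `"none"`.
#' @return an object of class `msz_scoring_params`.
#' @export
scoring_params <- function(fold_threshold = 5, tau = 1.0, pseudocount = 0,
                           normalization = c("cpm", "none")) {
  normalization <- match.arg(normalization)
  check_scalar_number(fold_threshold, "fold_threshold", lower = 1,
                      strict_lower = TRUE)
  check_scalar_number(tau, "tau", lower = 0)
  check_scalar_number(pseudocount, "pseudocount", lower = 0)
  structure(list(fold_threshold = fold_threshold, tau = tau,
                 pseudocount = pseudocount, normalization = normalization),
            class = "msz_scoring_params")
}

#' Normalize a count matrix to per-sample abundances
#'
#' CPM mode rescales every sample column to sum to one million; `none` is the
#' identity. An all-zero sample column is left all-zero with a warning.
#'
#' @param counts nonnegative gene x sample matrix (gene ids as rownames).
#' @param params an `msz_scoring_params`.
#' @return a numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts, params = scoring_params()) {
  check_count_matrix(counts)
  if (params$normalization == "none") {
    return(counts * 1.0)
  }
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with zero total counts left all-zero: ",
            paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    totals[zero] <- 1
  }
  sweep(counts, 2, totals, "/") * 1e6
}

#' Score one red/white abundance pair
#'
#' The screen's per-pair rule: a score of 2 if the red (MSZ) abundance is
#' significant (`>= tau`) while the white partner is exactly zero; otherwise
#' a score of 1 if the white abundance is positive and red is at least
#' `fold_threshold` times higher; otherwise 0. The zero-in-white test takes
#' precedence, as absence from the neighbouring compartment is the stronger
#' evidence class.
#'
#' Vectorized over `red` and `white`.
#'
#' @param red,white nonnegative abundances (same normalization as `tau`).
#' @param params an `msz_scoring_params`.
#' @return integer score(s) in \{0, 1, 2\}.
#' @examples
#' score_gene_pair(50, 5)   # fold 10 -> 1
#' score_gene_pair(20, 0)   # significant red, zero white -> 2
#' score_gene_pair(0.5, 0)  # red below the significance floor -> 0
#' score_gene_pair(4, 1)    # fold 4 < 5 -> 0
#' @export
score_gene_pair <- function(red, white, params = scoring_params()) {
  if (any(red < 0) || any(white < 0)) {
    stop("abundances must be nonnegative", call. = FALSE)
  }
  score2 <- white == 0 & red >= params$tau
  score1 <- !score2 & white > 0 & red >= params$fold_threshold * white
  as.integer(score2) * 2L + as.integer(score1)
}

# Resolve the (method, replicate) red/white pairing of a sample sheet against
# the columns of an abundance matrix. Errors name any unpaired sample.
resolve_pairs <- function(abundance, sheet) {
  required <- c("sample_id", "color", "method", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0L) {
    stop("sample sheet lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(abundance)
  not_in_sheet <- setdiff(samples, sheet$sample_id)
  if (length(not_in_sheet) > 0L) {
    stop("sample(s) not in the sample sheet: ",
         paste(not_in_sheet, collapse = ", "), call. = FALSE)
  }
  sheet <- sheet[sheet$sample_id %in% samples, , drop = FALSE]
  key <- paste(sheet$method, sheet$replicate, sep = "_")
  pairs <- lapply(split(seq_len(nrow(sheet)), key), function(idx) {
    sub <- sheet[idx, , drop = FALSE]
    red <- sub$sample_id[sub$color == "red"]
    white <- sub$sample_id[sub$color == "white"]
    if (length(red) != 1L || length(white) != 1L) {
      stop("unpaired sample(s) in (method, replicate) group '",
           paste(sub$method[1], sub$replicate[1], sep = ", "), "': ",
           paste(sub$sample_id, collapse = ", "), call. = FALSE)
    }
    tibble::tibble(pair_id = paste(sub$method[1], sub$replicate[1], sep = "_"),
                   method = sub$method[1], replicate = sub$replicate[1],
                   red = red, white = white)
  })
  pairs <- dplyr::bind_rows(pairs)
  dplyr::arrange(pairs, match(.data$red, samples))
}

#' Score every gene in every red/white pair
#'
#' Applies [score_gene_pair()] element-wise over a gene x pair grid defined
#' by the sample sheet, and records the reported fold-changes
#' (`red / (white + pseudocount)`, `NA` where white is zero and the
#' pseudocount is zero) and the per-pair log-fold `log(red+1) - log(white+1)`
#' used downstream as a ranking tie-break.
#'
#' @param abundance normalized gene x sample matrix (see
#'   [normalize_counts()]).
#' @param sheet sample sheet tibble with columns sample_id, color, method,
#'   replicate; every column of `abundance` must pair one red with one white
#'   sample per (method, replicate).
#' @param params an `msz_scoring_params`.
#' @return an object of class `msz_pair_scores`: list with `scores` (integer
#'   gene x pair matrix), `fold_changes`, `log_folds`, `pairs` (pair table)
#'   and `params`.
#' @export
score_all_pairs <- function(abundance, sheet, params = scoring_params()) {
  if (any(abundance < 0)) stop("abundances must be nonnegative", call. = FALSE)
  pairs <- resolve_pairs(abundance, sheet)
  red <- abundance[, pairs$red, drop = FALSE]
  white <- abundance[, pairs$white, drop = FALSE]
  scores <- matrix(score_gene_pair(red, white, params),
                   nrow = nrow(abundance),
                   dimnames = list(rownames(abundance), pairs$pair_id))
  folds <- red / (white + params$pseudocount)
  if (params$pseudocount == 0) folds[white == 0] <- NA_real_
  dimnames(folds) <- dimnames(scores)
  log_folds <- log(red + 1) - log(white + 1)
  dimnames(log_folds) <- dimnames(scores)
  structure(list(scores = scores, fold_changes = folds,
                 log_folds = log_folds, pairs = pairs, params = params),
            class = "msz_pair_scores")
}

#' @export
print.msz_pair_scores <- function(x, ...) {
  cat(sprintf("<msz_pair_scores> %d genes x %d pairs (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$pairs$pair_id, collapse = ", ")))
  invisible(x)
}
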