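#' Binarize a six-region expression table into detection calls
#'
#' Emulates calling RT-PCR bands: a gene is "detected" in a region when its
#' expression value is at least `delta` (closed threshold, so a value exactly
#' at `delta` counts as detected).
#'
#' @param regional long tibble with columns gene_id, region, value over the
#'   six fixed regions (see [msz_regions()]).
#' @param delta nonnegative detection threshold, in expression units.
#' @return a wide tibble, one row per gene: gene_id plus one logical column
#'   per region; carries `delta` as an attribute.
#' @export
binarize_regions <- function(regional, delta = 1.0) {
  check_scalar_number(delta, "delta", lower = 0)
  stopifnot(all(c("gene_id", "region", "value") %in% names(regional)))
  check_region_names(regional$region)
  if (any(regional$value < 0)) {
    stop("regional expression values must be nonnegative", call. = FALSE)
  }
  presence <- tidyr::pivot_wider(
    dplyr::mutate(regional, detected = .data$value >= delta),
    id_cols = "gene_id", names_from = "region", values_from = "detected",
    values_fill = FALSE
  )
  for (r in setdiff(msz_regions(), names(presence))) presence[[r]] <- FALSE
  presence <- presence[, c("gene_id", msz_regions())]
  attr(presence, "delta") <- delta
  presence
}

#' Keep candidates localized to the anterior primitive streak
#'
#' Reproduces the six-region localization filter: a candidate is kept when it
#' is detected in the anterior PS and in none of the caudal neural, anterior
#' neural, caudal PS, or non-neural ectoderm regions. Detection in the
#' anterior midline (which contains organizer derivatives) is permitted by
#' default; `require_midline = TRUE` additionally demands it.
#'
#' @param presence wide detection table from [binarize_regions()].
#' @param candidates character vector of candidate gene ids (order is
#'   preserved in the output).
#' @param require_midline must the gene also be detected in the anterior
#'   midline? Default `FALSE` (allowed but not required).
#' @return the subset of `candidates` passing the filter, in input order.
#' @export
regional_specificity_filter <- function(presence, candidates,
                                        require_midline = FALSE) {
  missing <- setdiff(candidates, presence$gene_id)
  if (length(missing) > 0L) {
    stop("candidate gene(s) absent from the regional table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(candidates, presence$gene_id)
  keep <- presence$anterior_PS[idx]
  for (r in disallowed_regions()) keep <- keep & !presence[[r]][idx]
  if (require_midline) keep <- keep & presence$anterior_midline[idx]
  candidates[keep]
}
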