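#' Apply the three stage-resolved marker criteria
#'
#' A mesodermal-stem-zone marker must (i) not be expressed during
#' gastrulation, (ii) be upregulated only in the anterior primitive streak at
#' the initiation of axial elongation, and (iii) retain anterior-PS
#' expression at every elongation timepoint. "Expressed" means value
#' `>= delta` (the same closed-threshold convention as the regional screen).
#'
#' By default criterion (ii) reads "only" strictly, so anterior-midline
#' expression at initiation disqualifies; set
#' `allow_midline_at_initiation = TRUE` to exempt the midline.
#'
#' @param stages long tibble with columns gene_id, stage, timepoint, region,
#'   value over the three fixed stages (see [msz_stages()]) and six regions;
#'   elongation may carry several timepoints.
#' @param candidates gene ids to call (must all be present in `stages`).
#' @param delta nonnegative expression threshold.
#' @param allow_midline_at_initiation exempt anterior_midline from the
#'   "no other region" clause of criterion (ii).
#' @return a tibble with one row per candidate: gene_id, the three criterion
#'   booleans (`c1_not_gastrulation`, `c2_anteriorPS_only_at_initiation`,
#'   `c3_retained_through_elongation`) and `is_marker`, their conjunction.
#' @export
apply_marker_criteria <- function(stages, candidates, delta = 1.0,
                                  allow_midline_at_initiation = FALSE) {
  check_scalar_number(delta, "delta", lower = 0)
  required <- c("gene_id", "stage", "timepoint", "region", "value")
  stopifnot(all(required %in% names(stages)))
  check_region_names(stages$region)
  unknown_stage <- setdiff(unique(stages$stage), msz_stages())
  if (length(unknown_stage) > 0L) {
    stop("unknown stage(s): ", paste(unknown_stage, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(candidates, stages$gene_id)
  if (length(missing) > 0L) {
    stop("candidate gene(s) absent from the stage table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(candidates) == 0L) {
    return(tibble::tibble(gene_id = character(),
                          c1_not_gastrulation = logical(),
                          c2_anteriorPS_only_at_initiation = logical(),
                          c3_retained_through_elongation = logical(),
                          is_marker = logical()))
  }
  sub <- stages[stages$gene_id %in% candidates, , drop = FALSE]
  check_stage_grid(sub, candidates)

  expressed <- sub$value >= delta
  aps <- sub$region == "anterior_PS"
  other <- !aps & !(allow_midline_at_initiation &
                      sub$region == "anterior_midline")

  by_gene <- function(flag, subset) {
    tapply(flag[subset], sub$gene_id[subset], all)[candidates]
  }
  gast <- sub$stage == "gastrulation"
  init <- sub$stage == "initiation"
  elong <- sub$stage == "elongation"

  c1 <- as.logical(by_gene(!expressed, gast))
  c2 <- as.logical(by_gene(expressed, init & aps) &
                     by_gene(!expressed, init & other))
  c3 <- as.logical(by_gene(expressed, elong & aps))

  tibble::tibble(
    gene_id = candidates,
    c1_not_gastrulation = c1,
    c2_anteriorPS_only_at_initiation = c2,
    c3_retained_through_elongation = c3,
    is_marker = c1 & c2 & c3
  )
}

# Every candidate must cover the full stage x timepoint x region grid;
# missing combinations are named in the error.
check_stage_grid <- function(sub, candidates) {
  st_tp <- unique(sub[, c("stage", "timepoint")])
  grid <- tidyr::expand_grid(st_tp, region = msz_regions())
  expected <- nrow(grid)
  n_el <- sum(st_tp$stage == "elongation")
  if (n_el < 1L) {
    stop("stage table has no elongation timepoint", call. = FALSE)
  }
  missing_stages <- setdiff(msz_stages(), unique(grid$stage))
  if (length(missing_stages) > 0L) {
    stop("stage table lacks stage(s): ",
         paste(missing_stages, collapse = ", "), call. = FALSE)
  }
  counts <- table(sub$gene_id)
  bad <- names(counts)[counts != expected]
  if (length(bad) > 0L) {
    g <- bad[1L]
    have <- sub[sub$gene_id == g, c("stage", "timepoint", "region")]
    miss <- dplyr::anti_join(grid, have,
                             by = c("stage", "timepoint", "region"))
    combos <- utils::head(
      sprintf("%s/t%d/%s", miss$stage, miss$timepoint, miss$region), 5L)
    stop("missing stage/region combination(s) for gene '", g, "': ",
         paste(combos, collapse = ", "),
         if (length(bad) > 1L) sprintf(" (and %d more gene(s))",
                                       length(bad) - 1L) else "",
         call. = FALSE)
  }
}

#' Compare marker calls against planted ground truth
#'
#' @param calls tibble from [apply_marker_criteria()] (needs gene_id and
#'   is_marker).
#' @param truth tibble with gene_id and gene_class; genes of class
#'   `msz_marker` are the true positives. Genes absent from `calls` count as
#'   negative calls.
#' @return a list with n_true_positive, n_false_positive, n_false_negative,
#'   precision and recall; 0/0 ratios are defined as 0.
#' @export
evaluate_recovery <- function(calls, truth) {
  stopifnot(all(c("gene_id", "is_marker") %in% names(calls)),
            all(c("gene_id", "gene_class") %in% names(truth)))
  unknown <- setdiff(calls$gene_id, truth$gene_id)
  if (length(unknown) > 0L) {
    stop("called gene(s) absent from truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  called <- calls$gene_id[calls$is_marker]
  positive <- truth$gene_id[truth$gene_class == "msz_marker"]
  tp <- length(intersect(called, positive))
  fp <- length(setdiff(called, positive))
  fn <- length(setdiff(positive, called))
  ratio0 <- function(num, den) if (den == 0) 0 else num / den
  list(n_true_positive = tp, n_false_positive = fp, n_false_negative = fn,
       precision = ratio0(tp, tp + fp), recall = ratio0(tp, tp + fn))
}
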