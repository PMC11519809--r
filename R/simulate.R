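#' Configure a synthetic paired red/white screening dataset
#'
#' Builds the parameter set for [generate_dataset()]. The defaults emulate the
#' experimental design of the screen: two capture methods (laser capture
#' microdissection and manual dissection), three biological replicate pairs
#' per method, and planted gene classes that exercise every downstream filter.
#' Method-specific noise reflects the known trade-off between the two capture
#' regimes: laser capture yields degraded, shallower libraries (extra
#' dispersion, dropout, reduced depth) while manual dissection is coarse
#' (cross-contamination between the red and white compartments).
#'
#' @param n_genes total number of simulated genes; classes not accounted for
#'   by `class_counts` are filled with `silent` genes (all-zero expectation).
#' @param class_counts named integer vector of planted class sizes. Classes:
#'   `msz_marker` (expressed by organizer-resident cells only, anterior
#'   primitive streak, on from initiation through elongation), `neural`,
#'   `paraxial` (neighbouring-compartment genes), `housekeeping` (everywhere,
#'   always), `gastrulation_transient` (marker-patterned but already on during
#'   gastrulation), `anteriorPS_nonspecific` (anterior PS plus a second
#'   region), `msz_like_transient` (marker-patterned but lost at the last
#'   elongation timepoint).
#' @param n_replicates_per_method biological replicate pairs per method.
#' @param methods ordered method names.
#' @param base_mean expected expression of an "on" gene, in count units at
#'   depth factor 1.
#' @param dispersion_by_method named per-method negative-binomial dispersion
#'   (variance = mu + dispersion * mu^2).
#' @param dropout_prob_by_method named per-method probability that an observed
#'   count is zeroed after sampling (models degraded laser-capture RNA).
#' @param contamination_by_method named per-method mixing fraction lambda:
#'   each red sample's expectation is `(1-lambda)*red + lambda*white` and
#'   symmetrically for white (models coarse manual dissection).
#' @param library_size_mean,library_size_cv mean and coefficient of variation
#'   of the per-sample depth factor (log-normal).
#' @param depth_factor_by_method named per-method multiplier on the depth
#'   factor (laser-capture libraries are shallower).
#' @param n_elongation_timepoints number of elongation-stage timepoints in the
#'   stage-resolved table (>= 1).
#' @param table_noise_sd standard deviation of optional additive Gaussian
#'   noise on the regional/stage tables (0 = noise-free, the default; the
#'   wet-lab readouts these tables emulate are binary band/stain calls).
#' @param seed integer seed; identical config + seed reproduces the dataset
#'   bit-for-bit.
#'
#' @return an object of class `msz_sim_config`.
#' @seealso [generate_dataset()]
#' @export
simulation_config <- function(n_genes = 400L,
                              class_counts = c(msz_marker = 4L,
                                               neural = 50L,
                                               paraxial = 50L,
                                               housekeeping = 50L,
                                               gastrulation_transient = 50L,
                                               anteriorPS_nonspecific = 50L,
                                               msz_like_transient = 50L),
                              n_replicates_per_method = 3L,
                              methods = c("laser", "manual"),
                              base_mean = 100,
                              dispersion_by_method = c(laser = 0.5, manual = 0.1),
                              dropout_prob_by_method = c(laser = 0.2, manual = 0),
                              contamination_by_method = c(laser = 0, manual = 0.1),
                              library_size_mean = 1.0,
                              library_size_cv = 0.2,
                              depth_factor_by_method = c(laser = 0.5, manual = 1.0),
                              n_elongation_timepoints = 3L,
                              table_noise_sd = 0,
                              seed = 1L) {
  config <- list(
    n_genes = n_genes,
    class_counts = class_counts,
    n_replicates_per_method = n_replicates_per_method,
    methods = methods,
    base_mean = base_mean,
    dispersion_by_method = dispersion_by_method,
    dropout_prob_by_method = dropout_prob_by_method,
    contamination_by_method = contamination_by_method,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    depth_factor_by_method = depth_factor_by_method,
    n_elongation_timepoints = n_elongation_timepoints,
    table_noise_sd = table_noise_sd,
    seed = seed
  )
  class(config) <- "msz_sim_config"
  validate_simulation_config(config)
  config
}

validate_simulation_config <- function(config) {
  check_scalar_number(config$n_genes, "n_genes", lower = 1)
  if (config$n_genes != as.integer(config$n_genes)) {
    stop_field("n_genes", "must be a whole number")
  }
  cc <- config$class_counts
  if (!is.numeric(cc) || is.null(names(cc))) {
    stop_field("class_counts", "must be a named numeric vector")
  }
  unknown <- setdiff(names(cc), setdiff(msz_gene_classes(), "silent"))
  if (length(unknown) > 0L) {
    stop_field("class_counts", paste0("unknown gene class(es): ",
                                      paste(unknown, collapse = ", ")))
  }
  if (any(cc < 0) || any(cc != as.integer(cc))) {
    stop_field("class_counts", "counts must be nonnegative whole numbers")
  }
  if (sum(cc) > config$n_genes) {
    stop_field("class_counts",
               sprintf("sum of class counts (%d) exceeds n_genes (%d)",
                       sum(cc), config$n_genes))
  }
  check_scalar_number(config$n_replicates_per_method,
                      "n_replicates_per_method", lower = 1)
  if (!is.character(config$methods) || length(config$methods) < 1L ||
      anyDuplicated(config$methods)) {
    stop_field("methods", "must be a non-empty vector of unique method names")
  }
  check_scalar_number(config$base_mean, "base_mean", lower = 0,
                      strict_lower = TRUE)
  check_named_per_method(config$dispersion_by_method, "dispersion_by_method",
                         config$methods, lower = 0, strict_lower = TRUE)
  check_named_per_method(config$dropout_prob_by_method,
                         "dropout_prob_by_method", config$methods,
                         lower = 0, upper = 1)
  check_named_per_method(config$contamination_by_method,
                         "contamination_by_method", config$methods,
                         lower = 0, upper = 1)
  check_scalar_number(config$library_size_mean, "library_size_mean",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(config$library_size_cv, "library_size_cv",
                      lower = 0, strict_lower = TRUE)
  check_named_per_method(config$depth_factor_by_method,
                         "depth_factor_by_method", config$methods,
                         lower = 0, strict_lower = TRUE)
  check_scalar_number(config$n_elongation_timepoints,
                      "n_elongation_timepoints", lower = 1)
  check_scalar_number(config$table_noise_sd, "table_noise_sd", lower = 0)
  check_scalar_number(config$seed, "seed")
  invisible(config)
}

# Gene ids: the four default MSZ markers are named after the screen's four
# confirmed genes; every other gene is "<class>_<index>".
make_gene_ids <- function(class_labels) {
  marker_names <- c("cWIF1_like", "cThPO_like", "cPTGDS_like", "cUCKL1_like")
  ids <- character(length(class_labels))
  for (cls in unique(class_labels)) {
    idx <- which(class_labels == cls)
    if (cls == "msz_marker" && length(idx) <= length(marker_names)) {
      ids[idx] <- marker_names[seq_along(idx)]
    } else {
      ids[idx] <- sprintf("%s_%03d", cls, seq_along(idx))
    }
  }
  ids
}

# Expected expression of each gene class in the two captured compartments
# (red = MSZ-resident cells of the anterior PS; white = neighbouring neural
# plate / paraxial mesoderm), before contamination, in units of base_mean.
compartment_profiles <- function(class_labels, base_mean) {
  red_on <- class_labels %in% c("msz_marker", "msz_like_transient",
                                "gastrulation_transient",
                                "anteriorPS_nonspecific", "housekeeping")
  white_on <- class_labels %in% c("neural", "paraxial", "housekeeping")
  list(red = ifelse(red_on, base_mean, 0),
       white = ifelse(white_on, base_mean, 0))
}

# Region sets where each class is "on" in the six-region localization table.
class_region_sets <- function() {
  list(
    msz_marker = c("anterior_PS", "anterior_midline"),
    msz_like_transient = "anterior_PS",
    gastrulation_transient = "anterior_PS",
    anteriorPS_nonspecific = c("anterior_PS", "non_neural_ectoderm"),
    neural = c("caudal_neural", "anterior_neural"),
    paraxial = "caudal_PS",
    housekeeping = msz_regions(),
    silent = character()
  )
}

#' Generate a seeded synthetic screening dataset with planted ground truth
#'
#' Draws a gene-by-sample count matrix, the paired red/white sample sheet, a
#' six-region expression table, a stage-resolved (gastrulation / initiation /
#' elongation) expression table, and the planted class label of every gene.
#'
#' Counts are negative binomial with per-sample mean
#' `depth * ((1-lambda) * own_compartment + lambda * other_compartment)` and
#' method-specific dispersion, followed by Bernoulli dropout zeroing. All
#' draws are made by inverse-CDF transforms of a fixed grid of uniform
#' deviates drawn once up-front, so that two configs differing only in, say,
#' the contamination fraction share their underlying randomness: sweeps over
#' noise parameters are coupled, which makes recovery curves smooth in the
#' swept parameter at a fixed seed.
#'
#' The regional and stage tables are noise-free by default (they stand in for
#' binary RT-PCR band calls and in-situ stain calls); `table_noise_sd` adds
#' truncated Gaussian noise if desired.
#'
#' @param config an `msz_sim_config` from [simulation_config()].
#' @return an object of class `msz_dataset`: a list with elements
#'   `counts` (integer gene x sample matrix), `samples` (tibble: sample_id,
#'   color, method, replicate), `regional` (long tibble: gene_id, region,
#'   value), `stages` (long tibble: gene_id, stage, timepoint, region, value)
#'   and `truth` (tibble: gene_id, gene_class), plus the `config`.
#' @examples
#' ds <- generate_dataset(simulation_config(seed = 7))
#' dim(ds$counts)
#' table(ds$truth$gene_class)
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)

  n_silent <- config$n_genes - sum(config$class_counts)
  class_labels <- c(rep(names(config$class_counts),
                        times = config$class_counts),
                    rep("silent", n_silent))
  gene_ids <- make_gene_ids(class_labels)
  truth <- tibble::tibble(gene_id = gene_ids, gene_class = class_labels)

  samples <- tidyr::expand_grid(
    method = config$methods,
    replicate = seq_len(config$n_replicates_per_method),
    color = c("red", "white")
  )
  samples <- dplyr::mutate(
    samples,
    sample_id = sprintf("%s_%d_%s", .data$method, .data$replicate, .data$color)
  )
  samples <- dplyr::select(samples, "sample_id", "color", "method", "replicate")
  n_samples <- nrow(samples)

  profiles <- compartment_profiles(class_labels, config$base_mean)

  # one uniform grid, drawn in a parameter-independent order
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  u_lib <- stats::runif(n_samples)
  u_counts <- matrix(stats::runif(config$n_genes * n_samples),
                     nrow = config$n_genes)
  u_drop <- matrix(stats::runif(config$n_genes * n_samples),
                   nrow = config$n_genes)
  u_tables <- stats::runif(2L)  # reserved draws keying optional table noise

  # per-sample log-normal depth factor with method-specific multiplier
  sdlog <- sqrt(log(1 + config$library_size_cv^2))
  meanlog <- log(config$library_size_mean) - sdlog^2 / 2
  depth <- stats::qlnorm(u_lib, meanlog = meanlog, sdlog = sdlog) *
    config$depth_factor_by_method[samples$method]

  counts <- matrix(0L, nrow = config$n_genes, ncol = n_samples,
                   dimnames = list(gene_ids, samples$sample_id))
  for (s in seq_len(n_samples)) {
    meth <- samples$method[s]
    lambda <- config$contamination_by_method[[meth]]
    own <- if (samples$color[s] == "red") profiles$red else profiles$white
    other <- if (samples$color[s] == "red") profiles$white else profiles$red
    mu <- depth[s] * ((1 - lambda) * own + lambda * other)
    size <- 1 / config$dispersion_by_method[[meth]]
    x <- stats::qnbinom(u_counts[, s], mu = mu, size = size)
    x[mu == 0] <- 0L
    p_drop <- config$dropout_prob_by_method[[meth]]
    if (p_drop > 0) x[u_drop[, s] < p_drop] <- 0L
    counts[, s] <- as.integer(x)
  }

  regional <- build_regional_table(gene_ids, class_labels, config, u_tables[1L])
  stages <- build_stage_table(gene_ids, class_labels, config, u_tables[2L])

  structure(list(counts = counts, samples = samples, regional = regional,
                 stages = stages, truth = truth, config = config),
            class = "msz_dataset")
}

build_regional_table <- function(gene_ids, class_labels, config, noise_key) {
  sets <- class_region_sets()
  grid <- tidyr::expand_grid(gene_id = gene_ids, region = msz_regions())
  grid$gene_class <- class_labels[match(grid$gene_id, gene_ids)]
  on <- unname(mapply(function(cls, reg) reg %in% sets[[cls]],
                      grid$gene_class, grid$region))
  grid$value <- ifelse(on, config$base_mean, 0)
  grid <- add_table_noise(grid, config$table_noise_sd, noise_key)
  dplyr::select(grid, "gene_id", "region", "value")
}

# Stage-resolved on/off design per class. Each class either follows the
# marker trajectory (off at gastrulation, anterior-PS-only from initiation)
# or violates exactly one criterion, so the criteria filter is identifiable
# on noise-free tables.
build_stage_table <- function(gene_ids, class_labels, config, noise_key) {
  n_el <- config$n_elongation_timepoints
  stage_grid <- dplyr::bind_rows(
    tibble::tibble(stage = "gastrulation", timepoint = 1L),
    tibble::tibble(stage = "initiation", timepoint = 1L),
    tibble::tibble(stage = "elongation", timepoint = seq_len(n_el))
  )
  grid <- tidyr::expand_grid(
    gene_id = gene_ids,
    stage_grid,
    region = msz_regions()
  )
  grid$gene_class <- class_labels[match(grid$gene_id, gene_ids)]

  aps <- grid$region == "anterior_PS"
  nne <- grid$region == "non_neural_ectoderm"
  neural_reg <- grid$region %in% c("caudal_neural", "anterior_neural")
  gast <- grid$stage == "gastrulation"
  last_el <- grid$stage == "elongation" & grid$timepoint == n_el

  on <- rep(FALSE, nrow(grid))
  cls <- grid$gene_class
  on[cls == "msz_marker" & aps & !gast] <- TRUE
  on[cls == "msz_like_transient" & aps & !gast & !last_el] <- TRUE
  on[cls == "gastrulation_transient" & aps] <- TRUE
  on[cls == "anteriorPS_nonspecific" & (aps | nne) & !gast] <- TRUE
  on[cls == "neural" & neural_reg] <- TRUE
  on[cls == "paraxial" & grid$region == "caudal_PS"] <- TRUE
  on[cls == "housekeeping"] <- TRUE

  grid$value <- ifelse(on, config$base_mean, 0)
  grid <- add_table_noise(grid, config$table_noise_sd, noise_key)
  dplyr::select(grid, "gene_id", "stage", "timepoint", "region", "value")
}

add_table_noise <- function(grid, sd, noise_key) {
  if (sd > 0) {
    # keyed off the main uniform grid so count draws are unaffected
    set.seed(as.integer(noise_key * .Machine$integer.max / 2))
    grid$value <- pmax(0, grid$value + stats::rnorm(nrow(grid), sd = sd))
  }
  grid
}

#' @export
print.msz_dataset <- function(x, ...) {
  cat(sprintf("<msz_dataset> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(x$config$methods, collapse = " + ")))
  tab <- table(factor(x$truth$gene_class, levels = msz_gene_classes()))
  cat("planted classes:\n")
  print(tab)
  invisible(x)
}
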