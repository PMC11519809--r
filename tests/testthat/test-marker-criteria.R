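test_that("each criterion flags its own violation", {
  full <- marker_stage_table("marker")
  calls <- apply_marker_criteria(full, "marker", delta = 1)
  expect_true(calls$is_marker)
  expect_true(all(unlist(calls[, c("c1_not_gastrulation",
                                   "c2_anteriorPS_only_at_initiation",
                                   "c3_retained_through_elongation")])))

  # expressed in the anterior PS during gastrulation -> criterion i fails
  gast_on <- full
  gast_on$value[gast_on$stage == "gastrulation" &
                  gast_on$region == "anterior_PS"] <- 10
  calls <- apply_marker_criteria(gast_on, "marker", delta = 1)
  expect_false(calls$c1_not_gastrulation)
  expect_true(calls$c2_anteriorPS_only_at_initiation)
  expect_true(calls$c3_retained_through_elongation)
  expect_false(calls$is_marker)

  # second region at initiation -> criterion ii fails
  init_leaky <- full
  init_leaky$value[init_leaky$stage == "initiation" &
                     init_leaky$region == "caudal_PS"] <- 10
  calls <- apply_marker_criteria(init_leaky, "marker", delta = 1)
  expect_false(calls$c2_anteriorPS_only_at_initiation)
  expect_false(calls$is_marker)

  # lost at one elongation timepoint -> criterion iii fails
  fades <- full
  fades$value[fades$stage == "elongation" & fades$timepoint == 2 &
                fades$region == "anterior_PS"] <- 0
  calls <- apply_marker_criteria(fades, "marker", delta = 1)
  expect_true(calls$c1_not_gastrulation)
  expect_true(calls$c2_anteriorPS_only_at_initiation)
  expect_false(calls$c3_retained_through_elongation)
  expect_false(calls$is_marker)
})

test_that("midline expression at initiation is disqualifying unless allowed", {
  tab <- marker_stage_table("g1")
  tab$value[tab$stage == "initiation" &
              tab$region == "anterior_midline"] <- 10
  strict <- apply_marker_criteria(tab, "g1", delta = 1)
  expect_false(strict$c2_anteriorPS_only_at_initiation)
  lenient <- apply_marker_criteria(tab, "g1", delta = 1,
                                   allow_midline_at_initiation = TRUE)
  expect_true(lenient$is_marker)
})

test_that("tightening delta never grows the marker set on clean tables", {
  ds <- generate_dataset(simulation_config(seed = 23L))
  cand <- ds$truth$gene_id
  sets <- lapply(c(1, 50, 100, 150), function(d) {
    calls <- apply_marker_criteria(ds$stages, cand, delta = d)
    calls$gene_id[calls$is_marker]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # any threshold within the on/off gap recovers exactly the planted markers
  expect_setequal(sets[[1]],
                  ds$truth$gene_id[ds$truth$gene_class == "msz_marker"])
  expect_setequal(sets[[3]],
                  ds$truth$gene_id[ds$truth$gene_class == "msz_marker"])
  expect_length(sets[[4]], 0)
})

test_that("planted confounder classes fail exactly their designed criterion", {
  ds <- generate_dataset(simulation_config(seed = 23L))
  calls <- apply_marker_criteria(ds$stages, ds$truth$gene_id, delta = 1)
  calls$gene_class <- ds$truth$gene_class[match(calls$gene_id,
                                                ds$truth$gene_id)]
  trans <- calls[calls$gene_class == "msz_like_transient", ]
  expect_true(all(trans$c1_not_gastrulation))
  expect_true(all(trans$c2_anteriorPS_only_at_initiation))
  expect_false(any(trans$c3_retained_through_elongation))
  gast <- calls[calls$gene_class == "gastrulation_transient", ]
  expect_false(any(gast$c1_not_gastrulation))
  expect_true(all(gast$c2_anteriorPS_only_at_initiation))
  expect_true(all(gast$c3_retained_through_elongation))
  markers <- calls[calls$gene_class == "msz_marker", ]
  expect_true(all(markers$is_marker))
})

test_that("incomplete stage grids are rejected with the gap named", {
  tab <- marker_stage_table("g1")
  holey <- tab[!(tab$stage == "elongation" & tab$timepoint == 3 &
                   tab$region == "anterior_PS"), ]
  expect_error(apply_marker_criteria(holey, "g1", delta = 1),
               "g1.*elongation")
  expect_error(apply_marker_criteria(tab, c("g1", "absent"), delta = 1),
               "absent")
  no_elong <- tab[tab$stage != "elongation", ]
  expect_error(apply_marker_criteria(no_elong, "g1", delta = 1),
               "elongation")
})

test_that("recovery metrics count true and false calls correctly", {
  truth <- tibble::tibble(
    gene_id = c(sprintf("m%d", 1:4), sprintf("x%d", 1:4)),
    gene_class = rep(c("msz_marker", "neural"), each = 4))
  call_tbl <- function(pos) {
    tibble::tibble(gene_id = truth$gene_id,
                   is_marker = truth$gene_id %in% pos)
  }
  perfect <- evaluate_recovery(call_tbl(sprintf("m%d", 1:4)), truth)
  expect_equal(perfect$precision, 1.0)
  expect_equal(perfect$recall, 1.0)
  none <- evaluate_recovery(call_tbl(character()), truth)
  expect_equal(none$precision, 0)   # 0/0 convention
  expect_equal(none$recall, 0)
  half <- evaluate_recovery(call_tbl(c("m1", "m2", "x1", "x2")), truth)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$n_true_positive, 2L)
  expect_equal(half$n_false_positive, 2L)
  expect_equal(half$n_false_negative, 2L)
})
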