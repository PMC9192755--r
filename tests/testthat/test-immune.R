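## Immune fixtures: one slide + IF pairs, cached.
fx_if_mac <- function(offset = c(5, -3, 0.01))
  fx_cached("if_mac", generate_if_pair(fx_slide()$truth, "CD68_CD163",
                                       offset = offset, seed = 77))

test_that("registration recovers the generator-recorded transform", {
  cells <- fx_cells()
  corners <- cbind(c(30, 350, 30, 350), c(30, 30, 350, 350))
  for (off in list(c(0, 0, 0), c(5, -3, 0.01))) {
    ifm <- generate_if_pair(fx_slide()$truth, "CD68_CD163",
                            offset = off, seed = 77)
    tf <- register_if_to_brightfield(ifm, cells)
    ## composing estimate with the true forward transform gives identity
    err <- sqrt(rowSums((apply_transform(tf, apply_transform(ifm$transform,
                                                             corners)) -
                           corners)^2))
    expect_lt(max(err), 0.5)
    expect_lt(abs(tf$rotation + off[3]), 0.005)
    expect_lt(tf$residual, 1.5)
  }
})

test_that("registration tolerates losing half the blobs", {
  ifm <- fx_if_mac()
  cells <- fx_cells()
  set.seed(5)
  half <- cells[sample.int(nrow(cells), nrow(cells) %/% 2), ]
  tf <- register_if_to_brightfield(ifm, half)
  corners <- cbind(c(30, 350, 30, 350), c(30, 30, 350, 350))
  err <- sqrt(rowSums((apply_transform(tf, apply_transform(ifm$transform,
                                                           corners)) -
                         corners)^2))
  expect_lt(max(err), 1)
})

test_that("registration refuses images without enough blobs", {
  sl <- generate_slide(fx_spec(seed = 13, n_macrophages = 2,
                               n_lymphocytes = 0))
  ifm <- generate_if_pair(sl$truth, "CD68_CD163", seed = 1)
  expect_error(register_if_to_brightfield(ifm, fx_cells()), ">= 10")
})

test_that("cell-to-blob matching is one-to-one with unmatched listed", {
  pts <- data.frame(cell_id = 1:5, x = c(10, 30, 50, 70, 90), y = 20)
  blobs <- data.frame(x = c(10, 30, 50, 70, 90), y = 20, intensity = 1,
                      channel = "CD68")
  m <- match_cells(pts, blobs, rigid_transform(), max_dist = 3)
  expect_equal(nrow(m$pairs), 5)
  expect_length(m$unmatched_blobs, 0)
  ## one extra blob -> exactly one unmatched blob
  blobs2 <- rbind(blobs, data.frame(x = 55, y = 60, intensity = 1,
                                    channel = "CD163"))
  m2 <- match_cells(pts, blobs2, rigid_transform(), max_dist = 3)
  expect_equal(nrow(m2$pairs), 5)
  expect_length(m2$unmatched_blobs, 1)
})

test_that("label transfer follows the either-marker rule and panel scoping", {
  cells <- data.frame(cell_id = 1:4, x = c(10, 30, 50, 70), y = 10)
  matching <- list(pairs = data.frame(cell_id = c(1, 3), blob = c(1, 2)))
  lab <- label_from_if(cells, matching, "CD68_CD163")
  expect_equal(as.character(lab$label), c("macrophage", "other",
                                          "macrophage", "other"))
  ## same matching under the lymphocyte panel labels lymphocytes instead:
  ## a CD3 blob match means nothing to the macrophage panel and vice versa
  lab2 <- label_from_if(cells, matching, "CD3_CD20")
  expect_equal(levels(lab2$label), c("lymphocyte", "other"))
})

test_that("IF-transferred labels agree with generator cell classes", {
  lab <- label_slide_from_if(fx_cells(), fx_if_mac(), "CD68_CD163")
  md <- fx_match_truth(lab, fx_slide()$truth)
  is_mac <- md$cell_class %in% c("tissue_macrophage", "alveolar_macrophage")
  expect_gte(mean(md$label[is_mac] == "macrophage"), 0.9)
  expect_gte(mean(md$label[!is_mac] == "other"), 0.98)
})

test_that("model selection rejects a constant classifier on separable data", {
  lab <- label_slide_from_if(fx_cells(), fx_if_mac(), "CD68_CD163")
  sl2 <- generate_slide(fx_spec(seed = 101, n_macrophages = 20))
  if2 <- generate_if_pair(sl2$truth, "CD68_CD163", seed = 102)
  pl2 <- separate_stains(sl2$image)
  verif <- list(list(cells = build_cells(pl2, detect_nuclei(pl2)),
                     true_count = count_if_positive_cells(if2)))
  m <- fit_immune_model(lab, verif, families = c("constant", "rf"), seed = 5)
  expect_equal(m$family, "rf")
  ## the selected family minimizes the verification count error
  expect_equal(m$selection_report$family[which.min(m$selection_report$count_ape)],
               m$family)
  ## deterministic selection
  m2 <- fit_immune_model(lab, verif, families = c("constant", "rf"), seed = 5)
  expect_equal(m2$family, m$family)
  expect_equal(m2$selection_report, m$selection_report)
  expect_error(fit_immune_model(lab, list(), families = c("rf", "lda")),
               "verification")
  expect_error(fit_immune_model(lab, verif, families = "rf"), "2 candidate")
})

test_that("immune prediction is accurate, orthogonal to PD-L1 bins", {
  lab <- label_slide_from_if(fx_cells(), fx_if_mac(), "CD68_CD163")
  truth <- fx_slide()$truth
  ## attach subtype labels for matched macrophages (pathologist-style)
  md <- match_points(as.matrix(truth[, c("x", "y")]),
                     as.matrix(lab[, c("x", "y")]), 5)
  lab$subtype_label <- NA_character_
  cls <- truth$cell_class[md$pairs[, 1]]
  lab$subtype_label[md$pairs[, 2]][cls == "tissue_macrophage"] <- "tissue"
  lab$subtype_label[md$pairs[, 2]][cls == "alveolar_macrophage"] <- "alveolar"

  sl2 <- generate_slide(fx_spec(seed = 101, n_macrophages = 20))
  if2 <- generate_if_pair(sl2$truth, "CD68_CD163", seed = 102)
  pl2 <- separate_stains(sl2$image)
  verif <- list(list(cells = build_cells(pl2, detect_nuclei(pl2)),
                     true_count = count_if_positive_cells(if2)))
  model <- fit_immune_model(lab, verif, families = c("rf", "lda"), seed = 5)

  cells <- classify_pdl1_positivity(fx_cells())
  pred <- predict_immune_cells(cells, list(macrophage = model))
  expect_identical(pred$pdl1_bin, cells$pdl1_bin)  # orthogonality
  ## macrophage count within 25% of truth on this small slide
  n_true <- sum(truth$cell_class %in% c("tissue_macrophage",
                                        "alveolar_macrophage"))
  expect_lte(abs(sum(pred$cell_class == "macrophage") - n_true),
             max(3, 0.25 * n_true))
  ## subtype head fills in tissue/alveolar for predicted macrophages
  expect_true(all(!is.na(pred$subtype[pred$cell_class == "macrophage"])))

  ## a PD-L1 positive macrophage in truth lands in the positive immune tally
  mdp <- fx_match_truth(pred, truth)
  posmac <- mdp[mdp$cell_class %in% c("tissue_macrophage",
                                      "alveolar_macrophage") &
                  mdp$pdl1_intensity >= 1, ]
  if (nrow(posmac) > 0)
    expect_gte(mean(posmac$pdl1_bin >= 1), 0.8)

  ## slides with no immune cells: false positive rate <= 10%
  sl0 <- generate_slide(fx_spec(seed = 55, n_macrophages = 0,
                                n_lymphocytes = 0))
  pl0 <- separate_stains(sl0$image)
  cells0 <- build_cells(pl0, detect_nuclei(pl0))
  pred0 <- predict_immune_cells(cells0, list(macrophage = model))
  expect_lte(mean(pred0$cell_class == "macrophage"), 0.10)

  bad <- model; bad$feature_hash <- "other"
  expect_error(predict_immune_cells(cells, list(macrophage = bad)), "hash")
})

test_that("IF counting dedups double positives and sees blank channels", {
  truth <- data.frame(id = 1:3, x = c(50, 120, 200), y = c(60, 140, 210),
                      nucleus_radius = 6, cell_class = "tissue_macrophage",
                      cd68 = c(TRUE, TRUE, FALSE),
                      cd163 = c(TRUE, FALSE, TRUE),
                      cd3 = FALSE, cd20 = FALSE)
  attr(truth, "width") <- 256; attr(truth, "height") <- 256
  ifm <- generate_if_pair(truth, "CD68_CD163", seed = 3)
  expect_equal(count_if_positive_cells(ifm, "CD68"), 2)
  expect_equal(count_if_positive_cells(ifm, "CD163"), 2)
  ## the double-positive cell counts once in the union
  expect_equal(count_if_positive_cells(ifm, "both"), 3)
  expect_error(count_if_positive_cells(ifm, "CD31"), "unknown channel")

  ifl <- generate_if_pair(truth, "CD3_CD20", seed = 4)
  expect_equal(count_if_positive_cells(ifl), 0)
})
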