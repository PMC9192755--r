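## Renders OD planes to 8-bit RGB directly in the test (independent of the
## package's internal renderer) for constructed fixtures.
render_rgb <- function(h_od, dab_od, basis = hdab_basis()) {
  d <- dim(h_od)
  arr <- array(0L, c(d, 3))
  for (k in 1:3) {
    od <- h_od * basis[1, k] + dab_od * basis[2, k]
    px <- round(256 * 10^(-od) - 1)
    arr[, , k] <- as.integer(pmin(pmax(px, 0), 255))
  }
  slide_image(arr, 0.5, "constructed")
}

## dome-profiled nucleus (dark centre, like stained chromatin)
disk_od <- function(dim, cx, cy, r, amp, dome = 0) {
  m <- matrix(0, dim[1], dim[2])
  for (y in seq_len(dim[1])) {
    d2 <- (seq_len(dim[2]) - 1 - cx)^2 + (y - 1 - cy)^2
    sel <- d2 <= r^2
    m[y, sel] <- amp * (1 - dome * d2[sel] / r^2)
  }
  m
}

test_that("stain separation recovers pure-stain and white pixels", {
  basis <- hdab_basis()
  dim2 <- c(8, 8)
  ## pure DAB
  img_d <- render_rgb(matrix(0, 8, 8), matrix(0.5, 8, 8))
  pl <- separate_stains(img_d)
  expect_gt(mean(pl$dab), 0.45)
  expect_lt(max(pl$h), 0.02)
  ## white pixels carry (almost) no stain: one quantization step of OD
  img_w <- slide_image(array(255L, c(4, 4, 3)), 0.5, "white")
  plw <- separate_stains(img_w)
  expect_lt(max(abs(c(plw$h, plw$dab, plw$res))), 5e-3)
  ## singular basis rejected
  bad <- basis; bad[2, ] <- bad[1, ]
  expect_error(separate_stains(img_w, bad), "singular")
})

test_that("stain separation round-trips a zero-noise slide within 1e-3 OD", {
  sp <- slide_spec(width = 256, height = 256, n_tumor_cells = 40,
                   n_stromal_cells = 30, n_macrophages = 5,
                   n_lymphocytes = 8, true_tps = 50,
                   background_intensity = 0.1, stain_noise_sd = 0, seed = 3)
  sl <- generate_slide(sp)
  pl <- separate_stains(sl$image)
  od <- -log10((sl$image$pixels + 1) / 256)
  rec <- reconstruct_od(pl)
  ## signed residual absorbs 8-bit quantization; only the clipped negative
  ## stain loadings remain, which are rare and tiny
  expect_lt(mean(abs(rec - od)), 1e-3)
  expect_lt(max(abs(rec - od)), 0.01)
})

test_that("nucleus detection finds isolated nuclei and splits touching ones", {
  ## blank image -> nothing
  blank <- slide_image(array(250L, c(64, 64, 3)), 0.5, "blank")
  expect_equal(max(detect_nuclei(separate_stains(blank))), 0)

  ## 50 well-separated nuclei on a grid
  hod <- matrix(0, 300, 300)
  centres <- as.matrix(expand.grid(x = seq(25, 275, length.out = 8),
                                   y = seq(25, 275, length.out = 7)))[1:50, ]
  for (i in 1:50)
    hod <- hod + disk_od(c(300, 300), centres[i, 1], centres[i, 2], 5, 0.6)
  img <- render_rgb(hod, matrix(0, 300, 300))
  lab <- detect_nuclei(separate_stains(img))
  cells <- build_cells(separate_stains(img), lab)
  m <- match_points(centres, as.matrix(cells[, c("x", "y")]), max_dist = 5)
  expect_gte(nrow(m$pairs), 45)
  expect_lte(length(m$unmatched_b), 2)
  d <- sqrt(rowSums((centres[m$pairs[, 1], ] -
                       as.matrix(cells[m$pairs[, 2], c("x", "y")]))^2))
  expect_true(all(d <= 3))

  ## two dome-profiled nuclei overlapping ~30 percent are split
  h2 <- pmax(disk_od(c(64, 64), 26, 32, 6, 0.65, dome = 0.35),
             disk_od(c(64, 64), 35, 32, 6, 0.65, dome = 0.35))
  lab2 <- detect_nuclei(separate_stains(render_rgb(h2, matrix(0, 64, 64))))
  expect_equal(max(lab2), 2)

  expect_error(detect_params(min_area = 100, max_area = 50), "degenerate")
})

test_that("membrane ring geometry and intensities behave as constructed", {
  ## isolated nucleus radius 5, ring_width 2: ring area ~ pi (7^2 - 5^2)
  h1 <- disk_od(c(64, 64), 32, 32, 5, 0.65)
  ring_od <- disk_od(c(64, 64), 32, 32, 8, 0.6) -
    disk_od(c(64, 64), 32, 32, 5.5, 0.6)
  img <- render_rgb(h1, pmax(ring_od, 0))
  pl <- separate_stains(img)
  cells <- build_cells(pl, detect_nuclei(pl), cell_params(ring_width = 2))
  expect_equal(nrow(cells), 1)
  ring <- attr(cells, "ring_labels")
  expect_gt(sum(ring == 1), 0.6 * pi * (7^2 - 5^2))
  expect_lt(sum(ring == 1), 1.5 * pi * (7^2 - 5^2))
  ## strong membrane: ring p90 above cytoplasm mean, ring complete
  expect_gt(cells$dab_ring_p90, cells$dab_cyto_mean)
  expect_gt(cells$ring_completeness, 0.9)
  expect_error(cell_params(ring_width = 0), "ring_width")
})

test_that("strong-membrane cells show ring DAB above cytoplasm on slides", {
  md <- fx_match_truth(fx_cells(), fx_slide()$truth)
  hi <- md[md$pdl1_intensity == 3 & md$cell_class == "tumor", ]
  expect_gt(nrow(hi), 0)
  expect_true(all(hi$dab_ring_p90 > hi$dab_cyto_mean))
})

test_that("feature extraction is deterministic and shift-consistent", {
  pl <- fx_planes()
  a <- build_cells(pl, detect_nuclei(pl))
  b <- build_cells(pl, detect_nuclei(pl))
  expect_identical(a, b)

  ## whole-pixel translation: identical features, shifted centroids
  sp <- slide_spec(width = 192, height = 192, n_tumor_cells = 20,
                   n_stromal_cells = 10, n_macrophages = 0, n_lymphocytes = 0,
                   true_tps = 50, stain_noise_sd = 0, seed = 8)
  sl <- generate_slide(sp)
  px <- sl$image$pixels
  bg <- px[1, 1, ]  # uniform zero-noise background
  sh <- array(0L, dim(px))
  for (k in 1:3) sh[, , k] <- bg[k]
  dx <- 6L; dy <- 4L
  sh[(dy + 1):192, (dx + 1):192, ] <- px[1:(192 - dy), 1:(192 - dx), ]
  c0 <- build_cells(separate_stains(sl$image), detect_nuclei(separate_stains(sl$image)))
  c1 <- build_cells(separate_stains(slide_image(sh, 0.5, "shift")),
                    detect_nuclei(separate_stains(slide_image(sh, 0.5, "shift"))))
  ## drop cells near the frame edge that the shift clipped
  keep <- c0$x < 192 - dx - 15 & c0$y < 192 - dy - 15 & c0$x > 12 & c0$y > 12
  m <- match_points(as.matrix(c0[keep, c("x", "y")]) +
                      matrix(rep(c(dx, dy), each = sum(keep)), ncol = 2),
                    as.matrix(c1[, c("x", "y")]), max_dist = 1)
  expect_equal(nrow(m$pairs), sum(keep))
  f0 <- as.matrix(c0[keep, FEATURE_NAMES])[m$pairs[, 1], ]
  f1 <- as.matrix(c1[, FEATURE_NAMES])[m$pairs[, 2], ]
  ## local_density can differ for cells whose neighbourhood was clipped
  comparable <- setdiff(FEATURE_NAMES, "local_density")
  expect_equal(f0[, comparable], f1[, comparable], tolerance = 1e-6)
})

test_that("background measurement tracks the generator's background OD", {
  sl <- fx_slide()
  pl <- fx_planes()
  bg <- measure_background(pl, fx_cells(), sl$annotations)
  expect_true(bg$acceptable)
  truth_bg <- 0.1 * 0.3  # background_intensity x 1+ OD anchor
  expect_lt(abs(bg$mean_dab_od - truth_bg) / truth_bg, 0.10)

  ## background raised above the 1+ threshold is unacceptable
  sp_hi <- fx_spec(seed = 12)
  sp_hi$background_intensity <- 0.75
  sl_hi <- generate_slide(sp_hi)
  pl_hi <- separate_stains(sl_hi$image)
  cells_hi <- build_cells(pl_hi, detect_nuclei(pl_hi))
  bg_hi <- measure_background(pl_hi, cells_hi, sl_hi$annotations)
  expect_false(bg_hi$acceptable)
})
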