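## Shared fixtures, generated once per test run and cached. Small canvases
## keep the unit suite fast; the acceptance tests use the generator defaults.

fixture_env <- new.env()

fx_cached <- function(name, expr) {
  if (is.null(fixture_env[[name]]))
    assign(name, force(expr), envir = fixture_env)
  fixture_env[[name]]
}

fx_spec <- function(seed = 42, true_tps = 40,
                    n_macrophages = 12, n_lymphocytes = 18) {
  slide_spec(width = 384, height = 384, n_tumor_cells = 90,
             n_stromal_cells = 70, n_macrophages = n_macrophages,
             n_lymphocytes = n_lymphocytes, true_tps = true_tps, seed = seed)
}

fx_slide <- function() fx_cached("slide", generate_slide(fx_spec()))

fx_planes <- function() fx_cached("planes", separate_stains(fx_slide()$image))

fx_cells <- function() fx_cached("cells", {
  p <- fx_planes()
  build_cells(p, detect_nuclei(p), slide_id = "fx")
})

fx_scored <- function() fx_cached("scored", {
  sl <- fx_slide()
  score_slide(sl$image, sl$annotations, config = score_config(policy = "raw"))
})

## map detected cells onto ground truth by mutual NN; returns data frame of
## matched pairs with truth class/intensity and detected columns
fx_match_truth <- function(cells, truth, max_dist = 5) {
  m <- match_points(as.matrix(truth[, c("x", "y")]),
                    as.matrix(cells[, c("x", "y")]), max_dist)
  cbind(truth[m$pairs[, 1], c("cell_class", "pdl1_intensity", "compartment")],
        cells[m$pairs[, 2], setdiff(names(cells), "compartment")],
        det_compartment = cells$compartment[m$pairs[, 2]])
}
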