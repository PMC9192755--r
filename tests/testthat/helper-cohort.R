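## Cohort-scale fixtures for the acceptance suite, cached across test files.
## These run the pipeline at the generator's default slide scale (640 px,
## ~430 cells) — the study conditions — and are therefore slower than the
## unit fixtures.

## One scored slide: returns truth, detected/scored cells and the TPS.
score_synthetic_slide <- function(spec, policy = "raw") {
  sl <- generate_slide(spec)
  out <- score_slide(sl$image, sl$annotations,
                     config = score_config(policy = policy))
  list(truth = sl$truth, cells = out$cells, tps = out$tps)
}

## 20-slide sweep with true TPS on the grid 0, 5, ..., 95 (fixed seeds).
acceptance_cohort <- function() {
  fx_cached("acc_cohort", lapply(1:20, function(i) {
    score_synthetic_slide(slide_spec(true_tps = 5 * (i - 1), seed = 1000 + i))
  }))
}

## Macrophage + lymphocyte models trained via the IF label-transfer path on
## a training set disjoint from every evaluation cohort.
acceptance_immune_models <- function() {
  fx_cached("acc_immune", {
    panels <- list(macrophage = "CD68_CD163", lymphocyte = "CD3_CD20")
    train_slides <- lapply(1:3, function(i)
      generate_slide(slide_spec(seed = 2000 + i, true_tps = 25 * i,
                                n_macrophages = 20 + 15 * i,
                                n_lymphocytes = 30 + 15 * i)))
    train_cells <- lapply(train_slides, function(sl) {
      p <- separate_stains(sl$image)
      build_cells(p, detect_nuclei(p))
    })
    verif_slides <- lapply(1:2, function(i)
      generate_slide(slide_spec(seed = 2100 + i, true_tps = 40,
                                n_macrophages = 15 + 20 * i,
                                n_lymphocytes = 25 + 25 * i)))
    verif_cells <- lapply(verif_slides, function(sl) {
      p <- separate_stains(sl$image)
      build_cells(p, detect_nuclei(p))
    })
    models <- lapply(names(panels), function(task) {
      panel <- panels[[task]]
      train <- do.call(rbind, lapply(seq_along(train_slides), function(i) {
        ifi <- generate_if_pair(train_slides[[i]]$truth, panel,
                                offset = c(3, -2, 0.004), seed = 2200 + i)
        label_slide_from_if(train_cells[[i]], ifi, panel)
      }))
      verif <- lapply(seq_along(verif_slides), function(i) {
        ifi <- generate_if_pair(verif_slides[[i]]$truth, panel,
                                offset = c(0, 0, 0), seed = 2300 + i)
        list(cells = verif_cells[[i]],
             true_count = count_if_positive_cells(ifi))
      })
      fit_immune_model(train, verif, families = c("rf", "lda"), seed = 11)
    })
    names(models) <- names(panels)
    models
  })
}

## 30 evaluation samples with immune loads spanning 0-80 macrophages and
## 0-120 lymphocytes: predicted counts on the PD-L1 image vs counts from
## the paired IF images.
acceptance_immune_eval <- function() {
  fx_cached("acc_immune_eval", {
    models <- acceptance_immune_models()
    rows <- lapply(1:30, function(i) {
      n_mac <- round(80 * (i - 1) / 29)
      n_lym <- round(120 * (i - 1) / 29)
      sl <- generate_slide(slide_spec(seed = 3000 + i, true_tps = 30,
                                      n_macrophages = n_mac,
                                      n_lymphocytes = n_lym))
      p <- separate_stains(sl$image)
      cells <- predict_immune_cells(build_cells(p, detect_nuclei(p)), models)
      if_m <- generate_if_pair(sl$truth, "CD68_CD163",
                               offset = c(2, 1, 0.003), seed = 3100 + i)
      if_l <- generate_if_pair(sl$truth, "CD3_CD20",
                               offset = c(-1, 2, -0.002), seed = 3200 + i)
      data.frame(pred_mac = sum(cells$cell_class == "macrophage"),
                 if_mac = count_if_positive_cells(if_m),
                 pred_lym = sum(cells$cell_class == "lymphocyte"),
                 if_lym = count_if_positive_cells(if_l))
    })
    do.call(rbind, rows)
  })
}

## Predicted immune counts across 3 serial sections of 20 samples.
acceptance_serial_counts <- function() {
  fx_cached("acc_serial", {
    models <- acceptance_immune_models()
    mac <- matrix(NA_real_, 20, 3)
    lym <- matrix(NA_real_, 20, 3)
    for (s in 1:20) {
      secs <- generate_serial_sections(
        slide_spec(seed = 4000 + s, true_tps = 30,
                   n_macrophages = 10 + 3 * s, n_lymphocytes = 20 + 4 * s),
        n_sections = 3, section_jitter_sd = 1.5)
      for (k in 1:3) {
        p <- separate_stains(secs[[k]]$image)
        cells <- predict_immune_cells(build_cells(p, detect_nuclei(p)),
                                      models)
        mac[s, k] <- sum(cells$cell_class == "macrophage")
        lym[s, k] <- sum(cells$cell_class == "lymphocyte")
      }
    }
    list(macrophage = mac, lymphocyte = lym)
  })
}
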