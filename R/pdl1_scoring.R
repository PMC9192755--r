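## PD-L1 positivity classification by membrane-OD threshold, Tumor
## Proportion Score computation and therapy binning, plus the full-slide
## scoring composition with markup rendering.

TPS_BINS <- c("no_therapy_lt1", "therapy_ge1", "therapy_high_ge50")

#' Scoring configuration
#'
#' The three OD cut points map the membrane p90 DAB OD to the ordinal
#' 0/1+/2+/3+ grades. Defaults are the midpoints between the renderer's
#' fixed grade anchors (0.05/0.30/0.60/0.90 OD) and are frozen: they are
#' calibrated once against the stain model and never adjusted per slide.
#'
#' @param od_cuts increasing cut points `(t1, t2, t3)`; a cell is PD-L1
#'   positive iff its membrane p90 DAB OD is `>= t1`.
#' @param policy TPS denominator policy: `"immune_corrected"` removes
#'   predicted immune cells from the tumor-compartment denominator;
#'   `"raw"` keeps every tumor-compartment cell.
#' @param seed seed used for model training inside [score_slide()].
#' @export
score_config <- function(od_cuts = c(0.175, 0.45, 0.75),
                         policy = c("immune_corrected", "raw"),
                         seed = 1L) {
  if (length(od_cuts) != 3 || any(diff(od_cuts) <= 0))
    stop("od_cuts must be three strictly increasing values t1 < t2 < t3")
  list(od_cuts = od_cuts, policy = match.arg(policy), seed = as.integer(seed))
}

#' Classify per-cell PD-L1 positivity
#'
#' Bins the membrane p90 DAB OD with half-open intervals: `< t1` is 0,
#' `[t1, t2)` is 1+, `[t2, t3)` is 2+, `>= t3` is 3+. Positive means
#' bin >= 1.
#'
#' @param cells table from [build_cells()].
#' @param config a [score_config()] (only `od_cuts` is used).
#' @return `cells` with `pdl1_bin` set.
#' @export
classify_pdl1_positivity <- function(cells, config = score_config()) {
  cuts <- config$od_cuts
  if (any(diff(cuts) <= 0)) stop("od_cuts must be strictly increasing")
  cells$pdl1_bin <- findInterval(cells$dab_ring_p90, cuts)
  cells
}

#' Bin a TPS value into the therapy decision categories
#'
#' Cut-offs are exact and left-closed on the upper bins: `< 1` no therapy,
#' `>= 1` therapy, `>= 50` high-expression therapy.
#'
#' @param tps TPS in percent.
#' @export
bin_tps <- function(tps) {
  if (any(is.na(tps)) || any(tps < 0 | tps > 100))
    stop("tps must be in [0, 100]")
  TPS_BINS[1 + (tps >= 1) + (tps >= 50)]
}

#' Compute the Tumor Proportion Score
#'
#' TPS = 100 x (tumor-compartment tumor cells with membrane PD-L1 grade
#' >= 1) / (all tumor-compartment tumor cells). Under the
#' `immune_corrected` policy, cells predicted macrophage or lymphocyte are
#' removed from both numerator and denominator; under `raw` every
#' tumor-compartment cell counts. A zero denominator flags the slide
#' unscorable.
#'
#' @param cells table with `compartment` and `pdl1_bin` assigned.
#' @param policy `"immune_corrected"` or `"raw"`.
#' @param slide_id identifier for the result.
#' @return object of class `tps_result`.
#' @export
compute_tps <- function(cells, policy = c("immune_corrected", "raw"),
                        slide_id = cells$slide_id[1]) {
  policy <- match.arg(policy)
  if (nrow(cells) > 0 && (all(is.na(cells$compartment)) ||
                          all(is.na(cells$pdl1_bin))))
    stop("compartments and pdl1_bin must be assigned before compute_tps")
  denom_sel <- !is.na(cells$compartment) & cells$compartment == "tumor"
  if (policy == "immune_corrected")
    denom_sel <- denom_sel & !(cells$cell_class %in% c("macrophage", "lymphocyte"))
  n_tumor <- sum(denom_sel)
  n_pos <- sum(denom_sel & cells$pdl1_bin >= 1)
  if (n_tumor == 0) {
    return(structure(list(slide_id = slide_id, n_tumor_cells = 0L,
                          n_positive_tumor_cells = 0L, tps = NA_real_,
                          bin = NA_character_, denominator_policy = policy,
                          unscorable = TRUE,
                          reason = "zero tumor-cell denominator"),
                     class = "tps_result"))
  }
  tps <- 100 * n_pos / n_tumor
  structure(list(slide_id = slide_id, n_tumor_cells = as.integer(n_tumor),
                 n_positive_tumor_cells = as.integer(n_pos), tps = tps,
                 bin = bin_tps(tps), denominator_policy = policy,
                 unscorable = FALSE, reason = NA_character_),
            class = "tps_result")
}

#' @export
print.tps_result <- function(x, ...) {
  if (isTRUE(x$unscorable))
    cat(sprintf("TPS [%s]: unscorable (%s)\n", x$slide_id, x$reason))
  else
    cat(sprintf("TPS [%s]: %.2f%% (%d/%d positive tumor cells) -> %s\n",
                x$slide_id, x$tps, x$n_positive_tumor_cells,
                x$n_tumor_cells, x$bin))
  invisible(x)
}

## Paint membrane rings of tumor cells into a markup copy of the image:
## PD-L1 positive red, negative blue.
render_markup <- function(img, cells) {
  px <- img$pixels
  ring <- attr(cells, "ring_labels")
  if (is.null(ring) || nrow(cells) == 0) return(img)
  tumor <- which(!is.na(cells$compartment) & cells$compartment == "tumor")
  pos_ids <- cells$cell_id[tumor][cells$pdl1_bin[tumor] >= 1]
  neg_ids <- setdiff(cells$cell_id[tumor], pos_ids)
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  sel_p <- ring %in% pos_ids; sel_n <- ring %in% neg_ids
  r[sel_p] <- 230L; g[sel_p] <- 30L; b[sel_p] <- 30L
  r[sel_n] <- 30L; g[sel_n] <- 60L; b[sel_n] <- 230L
  slide_image(array(c(r, g, b), dim(px)), img$microns_per_pixel,
              paste0(img$slide_id, "-markup"))
}

#' Score one slide end to end
#'
#' Composition of the whole pipeline: quality check, stain separation,
#' nucleus detection, feature extraction, compartment assignment, PD-L1
#' positivity classification, optional immune-cell prediction, TPS. The
#' pipeline contains no randomness at inference (classifier training uses
#' the configured seed), so re-running on identical inputs gives a
#' bit-identical result.
#'
#' @param img a [slide_image()].
#' @param annotations optional [annotation_set()]; training polygons are
#'   required unless a fitted `compartment_model` is supplied.
#' @param models list with optional elements `compartment` (a
#'   `compartment_model`) and `immune` (list of `immune_model`s as taken by
#'   [predict_immune_cells()]).
#' @param config a [score_config()].
#' @return list with `tps` (a `tps_result`), `cells` (the cell table),
#'   `markup` (a [slide_image()] with positive cells red, negative blue) and
#'   `qc` (the quality report).
#' @export
score_slide <- function(img, annotations = NULL, models = list(),
                        config = score_config()) {
  qc <- quality_check_image(img)
  if (!qc$pass) {
    res <- structure(list(slide_id = img$slide_id, n_tumor_cells = 0L,
                          n_positive_tumor_cells = 0L, tps = NA_real_,
                          bin = NA_character_,
                          denominator_policy = config$policy,
                          unscorable = TRUE,
                          reason = paste("QC failure:",
                                         paste(qc$reasons, collapse = ", "))),
                     class = "tps_result")
    return(list(tps = res, cells = NULL, markup = NULL, qc = qc))
  }
  planes <- separate_stains(img)
  nuclei <- detect_nuclei(planes)
  cells <- build_cells(planes, nuclei, slide_id = img$slide_id)
  cmodel <- models$compartment
  if (is.null(cmodel)) {
    if (is.null(annotations))
      stop("score_slide needs either a compartment model or annotations ",
           "with training polygons")
    lab <- harvest_training_cells(cells, annotations)
    cmodel <- fit_compartment_model(lab, seed = config$seed)
  }
  cells <- assign_compartments(cells, cmodel, annotations)
  cells <- classify_pdl1_positivity(cells, config)
  if (!is.null(models$immune))
    cells <- predict_immune_cells(cells, models$immune)
  policy <- if (is.null(models$immune) && config$policy == "immune_corrected")
    "immune_corrected" else config$policy
  tps <- compute_tps(cells, policy = policy, slide_id = img$slide_id)
  list(tps = tps, cells = cells, markup = render_markup(img, cells), qc = qc)
}
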