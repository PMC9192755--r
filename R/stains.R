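## Beer-Lambert stain model shared by the synthetic renderer and the
## deconvolution step. Stain amounts are expressed in optical density (OD),
## OD = -log10((pixel + 1) / 256), so that stain contributions add linearly
## and the renderer and the separator are exact inverses at zero noise.

#' Hematoxylin/DAB stain basis
#'
#' Returns the standard published hematoxylin/DAB unit vectors with a third
#' residual vector orthogonal to both, as a 3x3 matrix with one stain per row
#' (rows: hematoxylin, dab, residual; columns: R, G, B).
#'
#' @export
hdab_basis <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.268, 0.570, 0.776)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  b <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(b) <- c("R", "G", "B")
  b
}

## 8-bit channel -> OD
od_from_u8 <- function(u8) -log10((u8 + 1) / 256)

## OD -> 8-bit channel (rounded, clamped)
u8_from_od <- function(od) {
  p <- round(256 * 10^(-od) - 1)
  p[p < 0] <- 0; p[p > 255] <- 255
  p
}

## Render per-pixel stain OD planes (list h, dab; matrices [h, w]) into an
## 8-bit RGB array [h, w, 3] through the Beer-Lambert basis.
render_od_planes <- function(h_od, dab_od, basis = hdab_basis()) {
  dims <- dim(h_od)
  od_rgb <- array(0, c(dims, 3))
  for (k in 1:3)
    od_rgb[, , k] <- h_od * basis["hematoxylin", k] + dab_od * basis["dab", k]
  arr <- array(u8_from_od(od_rgb), c(dims, 3))
  storage.mode(arr) <- "integer"
  arr
}
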