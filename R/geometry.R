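## Shared geometry helpers: point-in-polygon, mutual-nearest matching, rigid
## transforms. Coordinates are 0-based, x right / y down, pixel centers at
## integer positions.

#' Test points against a polygon (even-odd rule, strictly inside)
#'
#' Points lying exactly on an edge or vertex are counted as outside; this is
#' the documented convention used everywhere a cell centroid is tested against
#' an annotation polygon.
#'
#' @param x,y numeric vectors of point coordinates (pixels).
#' @param poly two-column matrix of polygon vertices (x, y); an open ring is
#'   closed implicitly.
#' @return logical vector, `TRUE` where the point is strictly inside.
#' @export
points_in_polygon <- function(x, y, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) >= 2 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 3) stop("polygon needs at least 3 distinct vertices")
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  jx <- px[c(n, seq_len(n - 1))]; jy <- py[c(n, seq_len(n - 1))]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- jx[i]; y2 <- jy[i]
    crosses <- ((y1 > y) != (y2 > y))
    if (any(crosses)) {
      xint <- x1 + (y[crosses] - y1) / (y2 - y1) * (x2 - x1)
      flip <- rep(FALSE, length(x)); flip[crosses] <- x[crosses] < xint
      inside <- xor(inside, flip)
      on_edge[crosses][abs(x[crosses] - xint) < 1e-9] <- TRUE
    }
    # horizontal / general on-segment check
    d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    tpar <- ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / max(len2, 1e-12)
    on_edge <- on_edge | (d < 1e-9 * sqrt(max(len2, 1)) & tpar >= 0 & tpar <= 1)
  }
  inside & !on_edge
}

#' Mutual nearest-neighbour matching of two point sets
#'
#' @param a,b two-column matrices (x, y).
#' @param max_dist maximum allowed pair distance in pixels.
#' @return list with `pairs` (two-column integer matrix of row indices into
#'   `a` and `b`), `unmatched_a`, `unmatched_b`.
#' @export
match_points <- function(a, b, max_dist = 5) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L)
    return(list(pairs = matrix(integer(), 0, 2),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb)))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  nn_ab <- apply(d2, 1, which.min)        # for each a, nearest b
  nn_ba <- apply(d2, 2, which.min)        # for each b, nearest a
  ia <- seq_len(na)
  mutual <- nn_ba[nn_ab] == ia &
    d2[cbind(ia, nn_ab)] <= max_dist^2
  pairs <- cbind(a = ia[mutual], b = nn_ab[mutual])
  list(pairs = pairs,
       unmatched_a = setdiff(ia, pairs[, 1]),
       unmatched_b = setdiff(seq_len(nb), pairs[, 2]))
}

#' Rigid 2-D transform (rotation about a centre, then translation)
#'
#' Represents `p' = R(theta) (p - centre) + centre + (dx, dy)`.
#'
#' @param dx,dy translation in pixels.
#' @param rotation rotation angle in radians (positive = x-to-y).
#' @param centre rotation centre (x, y); defaults to the origin.
#' @param residual mean matched-point distance after alignment (pixels).
#' @export
rigid_transform <- function(dx = 0, dy = 0, rotation = 0,
                            centre = c(0, 0), residual = NA_real_) {
  structure(list(dx = dx, dy = dy, rotation = rotation,
                 centre = centre, residual = residual),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param tf a [rigid_transform()].
#' @param pts two-column matrix (x, y).
#' @export
apply_transform <- function(tf, pts) {
  pts <- as.matrix(pts)
  ct <- cos(tf$rotation); st <- sin(tf$rotation)
  xc <- pts[, 1] - tf$centre[1]; yc <- pts[, 2] - tf$centre[2]
  cbind(ct * xc - st * yc + tf$centre[1] + tf$dx,
        st * xc + ct * yc + tf$centre[2] + tf$dy)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @export
invert_transform <- function(tf) {
  # p = R^-1 (p' - centre - t) + centre
  ct <- cos(-tf$rotation); st <- sin(-tf$rotation)
  # rewrite as rotation about the same centre plus a translation
  tx <- -tf$dx; ty <- -tf$dy
  rigid_transform(dx = ct * tx - st * ty, dy = st * tx + ct * ty,
                  rotation = -tf$rotation, centre = tf$centre,
                  residual = tf$residual)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: dx=%.3f dy=%.3f rot=%.5f rad (residual %.3f px)\n",
              x$dx, x$dy, x$rotation, x$residual))
  invisible(x)
}

## Run code with a private RNG stream, restoring .Random.seed afterwards.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
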