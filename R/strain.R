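# Strain maps from displacement fields: hydrostatic (mean normal) and
# engineering shear strain by central differencing over the vector grid,
# normalised by the characteristic initial length (the node spacing).

# Central differences with one-sided edges; returns dm/dx (along columns)
# or dm/dy (along rows), already divided by the node spacing h.
.gradAlong <- function(m, h, dim = c("x", "y")) {
  dim <- match.arg(dim)
  if (dim == "y") return(t(.gradAlong(t(m), h, "x")))
  n <- ncol(m)
  if (n < 2) stop("degenerate grid: need at least 2 nodes per axis")
  g <- matrix(NA_real_, nrow(m), n)
  if (n > 2) g[, 2:(n - 1)] <- (m[, 3:n] - m[, 1:(n - 2)]) / (2 * h)
  g[, 1] <- (m[, 2] - m[, 1]) / h
  g[, n] <- (m[, n] - m[, n - 1]) / h
  g
}

#' Strain field from a displacement field
#'
#' Spatial derivatives of u and v are taken by central differences across
#' adjacent grid nodes (one-sided at the edges), each normalised by the
#' node spacing L_char, the characteristic initial length before
#' deformation. The hydrostatic strain is the mean normal strain
#' (du/dx + dv/dy)/2; the shear strain is the engineering sum
#' du/dy + dv/dx (no factor 1/2).
#'
#' @param field a [DisplacementField-class] with a regular grid and at
#'   least 50 % valid-vector coverage.
#' @return a [StrainField-class]; strains are dimensionless (1 = 100 %).
#' @export
strainFromDisplacement <- function(field) {
  if (length(field@gridX) < 2 || length(field@gridY) < 2)
    stop("degenerate grid: need at least 2 nodes per axis")
  sp <- gridSpacing(field)
  if (length(unique(round(sp, 9))) != 1)
    stop("displacement grid must be regular")
  if (mean(field@valid | is.finite(field@u)) < 0.5)
    stop("less than 50% vector coverage")
  h <- sp[1]
  dudx <- .gradAlong(field@u, h, "x")
  dudy <- .gradAlong(field@u, h, "y")
  dvdx <- .gradAlong(field@v, h, "x")
  dvdy <- .gradAlong(field@v, h, "y")
  new("StrainField",
      hydro = (dudx + dvdy) / 2,
      shear = dudy + dvdx,
      gridX = field@gridX, gridY = field@gridY, Lchar = h)
}

#' Upsample a grid map to image resolution
#'
#' Bilinear interpolation of node values to every pixel; pixels outside
#' the grid hull take the nearest node value (clamped coordinates), and an
#' optional mask sets everything outside it to NA.
#'
#' @param strain a [StrainField-class], or a plain matrix together with
#'   `gridX`/`gridY`.
#' @param imageShape integer(2) (height, width) px.
#' @param component "hydro" or "shear" when `strain` is a StrainField.
#' @param mask optional logical matrix (e.g. the nucleus interior).
#' @param gridX,gridY node coordinates when `strain` is a plain matrix.
#' @return numeric matrix of `imageShape`.
#' @export
upsampleToImage <- function(strain, imageShape,
                            component = c("hydro", "shear"),
                            mask = NULL, gridX = NULL, gridY = NULL) {
  if (is(strain, "StrainField")) {
    component <- match.arg(component)
    m <- slot(strain, component)
    gridX <- strain@gridX; gridY <- strain@gridY
  } else {
    m <- strain
  }
  if (!length(m) || all(is.na(m))) stop("empty strain field")
  H <- imageShape[1]; W <- imageShape[2]
  hx <- if (length(gridX) > 1) gridX[2] - gridX[1] else 1
  hy <- if (length(gridY) > 1) gridY[2] - gridY[1] else 1
  ix <- pmin(pmax((seq_len(W) - gridX[1]) / hx + 1, 1), length(gridX))
  iy <- pmin(pmax((seq_len(H) - gridY[1]) / hy + 1, 1), length(gridY))
  gr <- expand.grid(y = iy, x = ix)
  out <- matrix(interpBilinear(m, gr$x, gr$y), H, W)
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Displacement-magnitude map at image resolution
#'
#' Convenience wrapper: upsamples |(u, v)| of a displacement field to pixel
#' resolution, in um when the field carries a pixel size.
#'
#' @param field a [DisplacementField-class].
#' @param imageShape integer(2) (height, width) px.
#' @param mask optional logical matrix.
#' @param units "um" (default, requires a pixel size) or "px".
#' @return numeric matrix of displacement magnitudes.
#' @export
displacementMagnitudeMap <- function(field, imageShape, mask = NULL,
                                     units = c("um", "px")) {
  units <- match.arg(units)
  mag <- sqrt(field@u^2 + field@v^2)
  if (units == "um") {
    if (is.na(field@pixelSize)) stop("field has no pixel size")
    mag <- mag * field@pixelSize
  }
  upsampleToImage(mag, imageShape, mask = mask,
                  gridX = field@gridX, gridY = field@gridY)
}
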