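#' Equal-area analysis frame
#'
#' All layers in an analysis (species rasters, site polygons, grids) share one
#' planar equal-area frame: a row-major grid of square cells of side
#' `cell_km`, origin at the lower-left corner, x increasing with column index
#' and y increasing upward (so row 1 is the top of the grid but carries the
#' largest y). Every cell has area `cell_km^2`, which is the property the
#' overlap analysis actually relies on.
#'
#' @param rows,cols Grid dimensions (number of cells).
#' @param cell_km Cell side length in kilometres.
#' @param origin Numeric length-2, km coordinates of the grid's lower-left
#'   corner. Defaults to `c(0, 0)`.
#' @return An object of class `grid_frame`.
#' @export
grid_frame <- function(rows, cols, cell_km, origin = c(0, 0)) {
  if (length(rows) != 1L || length(cols) != 1L || rows < 1 || cols < 1 ||
      rows != round(rows) || cols != round(cols)) {
    stop("`rows` and `cols` must be positive whole numbers", call. = FALSE)
  }
  if (!is.numeric(cell_km) || length(cell_km) != 1L || !is.finite(cell_km) ||
      cell_km <= 0) {
    stop("`cell_km` must be a positive number", call. = FALSE)
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         cell_km = as.numeric(cell_km), origin = as.numeric(origin)),
    class = "grid_frame"
  )
}

#' @export
print.grid_frame <- function(x, ...) {
  cat(sprintf("<grid_frame> %d x %d cells of %g km (area %g km^2/cell)\n",
              x$rows, x$cols, x$cell_km, x$cell_km^2))
  invisible(x)
}

#' Area of one grid cell in km^2
#' @param frame A [grid_frame()].
#' @export
cell_area <- function(frame) frame$cell_km^2

# Cell index <-> coordinate helpers. Cells are indexed 1..rows*cols in
# column-major order (R matrix convention): cell = (col - 1) * rows + row.
cell_row <- function(frame, cell) ((cell - 1L) %% frame$rows) + 1L
cell_col <- function(frame, cell) ((cell - 1L) %/% frame$rows) + 1L

#' Km coordinates of cell centres
#'
#' @param frame A [grid_frame()].
#' @param cells Integer cell indices (column-major); defaults to all cells.
#' @return A two-column matrix of x, y centre coordinates in km.
#' @export
cell_centers <- function(frame, cells = seq_len(frame$rows * frame$cols)) {
  r <- cell_row(frame, cells)
  c <- cell_col(frame, cells)
  cbind(x = frame$origin[1] + (c - 0.5) * frame$cell_km,
        y = frame$origin[2] + (frame$rows - r + 0.5) * frame$cell_km)
}

#' Do two layers share the same frame?
#' @param a,b `grid_frame` objects (or objects carrying a `frame` attribute).
#' @export
same_frame <- function(a, b) {
  fa <- if (inherits(a, "grid_frame")) a else attr(a, "frame")
  fb <- if (inherits(b, "grid_frame")) b else attr(b, "frame")
  if (is.null(fa) || is.null(fb)) return(FALSE)
  isTRUE(all.equal(unclass(fa), unclass(fb), tolerance = 1e-12))
}

stop_if_frame_mismatch <- function(a, b) {
  if (!same_frame(a, b)) {
    stop("layers are not in the same analysis frame; align them first ",
         "with align_projection()", call. = FALSE)
  }
  invisible(TRUE)
}

#' Affine transform between planar frames
#'
#' Represents the map `x -> A x + b` taking coordinates of one planar frame
#' into another. Equal-area transforms have `abs(det(A)) == 1`; areas scale
#' by `abs(det(A))` in general.
#'
#' @param a Numeric 2x2 matrix.
#' @param b Numeric length-2 offset (km).
#' @export
affine_transform <- function(a = diag(2), b = c(0, 0)) {
  a <- matrix(as.numeric(a), 2, 2)
  if (abs(det(a)) < 1e-15) stop("transform is singular", call. = FALSE)
  structure(list(a = a, b = as.numeric(b)), class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> det =", det(x$a), " shift =", x$b, "\n")
  invisible(x)
}

#' Invert an affine transform
#' @param x An [affine_transform()].
#' @export
invert_transform <- function(x) {
  ai <- solve(x$a)
  affine_transform(ai, -as.vector(ai %*% x$b))
}

apply_transform <- function(xy, tr) {
  sweep(xy %*% t(tr$a), 2, -tr$b)
}

#' Re-project a vector layer into the analysis frame
#'
#' Applies an affine transform to every vertex of a polygon or point layer so
#' that all layers share one equal-area frame. This is the synthetic-frame
#' analogue of re-projecting site boundaries to match the equal-area
#' projection of the species rasters. The layer must carry frame metadata
#' (a `frame` attribute); a layer of unknown provenance cannot be aligned.
#'
#' @param layer A `raw_sites` collection, a list of rings (two-column
#'   matrices), or a two-column coordinate matrix, with a `frame` attribute.
#' @param transform An [affine_transform()] mapping the layer's frame into
#'   `target`.
#' @param target The destination frame (recorded as the new `frame`
#'   attribute).
#' @return The layer with transformed coordinates and `frame = target`.
#' @export
align_projection <- function(layer, transform = affine_transform(),
                             target = attr(layer, "frame")) {
  if (is.null(attr(layer, "frame"))) {
    stop("layer carries no frame metadata; cannot align", call. = FALSE)
  }
  if (!inherits(transform, "affine_transform")) {
    stop("`transform` must be an affine_transform", call. = FALSE)
  }
  out <- transform_coords(layer, transform)
  attr(out, "frame") <- target
  out
}

transform_coords <- function(layer, tr) {
  if (is.matrix(layer)) {
    out <- apply_transform(layer, tr)
    extra <- setdiff(names(attributes(layer)), c("dim", "dimnames"))
    for (nm in extra) attr(out, nm) <- attr(layer, nm)
    return(out)
  }
  if (is.list(layer) && !is.null(layer$rings)) {
    layer$rings <- lapply(layer$rings, apply_transform, tr = tr)
    return(layer)
  }
  if (is.list(layer)) {
    out <- lapply(layer, transform_coords, tr = tr)
    attributes(out) <- attributes(layer)
    return(out)
  }
  stop("unsupported layer type", call. = FALSE)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards (so generators are reproducible without
# clobbering the session RNG).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
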