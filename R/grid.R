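#' Regular Cartesian grid specification
#'
#' Describes the rectangular domain on which all fields live: the number of
#' cells per axis and the physical spacing (e.g. mm) per axis. Grids are
#' cell-centered with 0-based integer cell indices in all logs and click
#' files; axis order is (row, col\[, slice\]).
#'
#' @param shape integer vector of extents per axis (length 2 or 3), all >= 8.
#' @param spacing numeric vector of physical cell sizes per axis (recycled to
#'   the length of `shape`), all > 0. Default 1.
#' @return an object of class `grid_spec` with elements `shape`, `spacing`.
#' @examples
#' g <- grid_spec(c(64, 64))
#' cell_volume(g)
#' @export
grid_spec <- function(shape, spacing = 1) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L))
    stop("grid must have 2 or 3 axes, got ", length(shape))
  if (any(shape < 8L))
    stop("all grid extents must be >= 8")
  spacing <- rep_len(as.numeric(spacing), length(shape))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all grid spacings must be finite and > 0")
  structure(list(shape = shape, spacing = spacing), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", paste(x$shape, collapse = " x "),
      " cells, spacing (", paste(format(x$spacing), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Physical volume of one grid cell
#' @param grid a `grid_spec`.
#' @return scalar, the product of the per-axis spacings.
#' @export
cell_volume <- function(grid) prod(grid$spacing)

#' Number of spatial dimensions of a grid or field
#' @param x a `grid_spec` or `scalar_field`.
#' @return 2 or 3.
#' @export
ndim <- function(x) {
  if (inherits(x, "scalar_field")) length(x$grid$shape) else length(x$shape)
}

#' Scalar field on a regular grid
#'
#' A real-valued quantity sampled at every cell of a [grid_spec()]: the image
#' intensity, a speed field, the accumulated user-input field, and so on.
#' Values must be finite everywhere.
#'
#' @param values numeric array whose `dim` matches `grid$shape` (a plain
#'   matrix for 2-D grids); a scalar is recycled.
#' @param grid a `grid_spec`.
#' @return an object of class `scalar_field` with elements `values`, `grid`.
#' @export
scalar_field <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L) values <- array(values, dim = grid$shape)
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("field dimensions ", paste(dim(values), collapse = "x"),
         " do not match grid ", paste(grid$shape, collapse = "x"))
  if (any(!is.finite(values)))
    stop("scalar_field values must be finite (no NA/NaN/Inf)")
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat("<", class(x)[1L], "> ", paste(dim(x$values), collapse = " x "),
      ", range [", format(min(x$values)), ", ", format(max(x$values)), "]",
      if (!is.null(x$eps)) paste0(", eps = ", format(x$eps)), "\n", sep = "")
  invisible(x)
}

#' Level-set field
#'
#' The evolving implicit function phi (and, with the same layout, the
#' reference psi and the observer estimate psi-hat). Positive values mark the
#' interior of the segmented region; the boundary is the zero level set. The
#' narrowband half-width `eps` (in grid units) bounds where the regularized
#' delta is nonzero and hence where the PDE acts. After redistancing the
#' gradient magnitude on the band lies in `[p1, p2]` and the curvature
#' magnitude below `kappa0` (see [redistance()]).
#'
#' @param values numeric array of signed values (interior positive).
#' @param grid a `grid_spec`.
#' @param eps narrowband half-width in grid units, > 0. Default 1.5.
#' @param p1,p2 admissible gradient-magnitude bounds on the band after
#'   redistancing. Defaults 0.8 and 1.2.
#' @param kappa0 admissible curvature bound on the band after redistancing;
#'   default `2 / min(spacing)`.
#' @return an object of class `level_set` (inherits `scalar_field`).
#' @export
level_set <- function(values, grid, eps = 1.5, p1 = 0.8, p2 = 1.2,
                      kappa0 = NULL) {
  f <- scalar_field(values, grid)
  if (!is.finite(eps) || eps <= 0) stop("narrowband half-width eps must be > 0")
  if (is.null(kappa0)) kappa0 <- 2 / min(grid$spacing)
  f$eps <- eps
  f$p1 <- p1
  f$p2 <- p2
  f$kappa0 <- kappa0
  class(f) <- c("level_set", class(f))
  f
}

#' Replace the values of a field, keeping its metadata
#' @param field a `scalar_field` or `level_set`.
#' @param values replacement array of the same dimensions.
#' @return a field of the same class.
#' @export
with_values <- function(field, values) {
  if (any(!is.finite(values))) stop("replacement values must be finite")
  if (length(values) == 1L) values <- array(values, dim = dim(field$values))
  dim(values) <- dim(field$values)
  storage.mode(values) <- "double"
  field$values <- values
  field
}

same_grid <- function(a, b) {
  identical(a$grid$shape, b$grid$shape) &&
    isTRUE(all.equal(a$grid$spacing, b$grid$spacing))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("fields are defined on different grids")
  invisible(TRUE)
}

#' Binary interior mask of a level-set field
#' @param phi a `level_set` (or any `scalar_field`).
#' @return logical array, `TRUE` where values > 0.
#' @export
interior_mask <- function(phi) phi$values > 0
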