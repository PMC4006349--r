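# Finite-difference primitives on 2-D/3-D arrays with replicate (Neumann)
# boundaries. All operators honor anisotropic spacing and share one code path
# for both dimensionalities.

# w[i] = v[i + s] along `axis`, clamped at the borders (replicate).
axshift <- function(v, axis, s) {
  d <- dim(v)
  idx <- pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
  args <- rep(list(quote(expr = )), length(d))
  args[[axis]] <- idx
  do.call(`[`, c(list(v), args, list(drop = FALSE)))
}

# Central difference along one axis.
central_diff <- function(v, axis, h) {
  (axshift(v, axis, 1L) - axshift(v, axis, -1L)) / (2 * h)
}

# List of central-difference gradient components of an array.
grad_components <- function(v, spacing) {
  lapply(seq_along(dim(v)), function(a) central_diff(v, a, spacing[a]))
}

# Euclidean norm of the central-difference gradient.
grad_norm_arr <- function(v, spacing) {
  g <- grad_components(v, spacing)
  sqrt(Reduce(`+`, lapply(g, function(x) x * x)))
}

#' Gradient-magnitude field
#'
#' Central-difference Euclidean gradient norm with replicate boundaries.
#'
#' @param field a `scalar_field`.
#' @return a `scalar_field` of |grad F|.
#' @export
gradient_norm <- function(field) {
  scalar_field(grad_norm_arr(field$values, field$grid$spacing), field$grid)
}

#' Mean-curvature operator kappa(F) = div(grad F / |grad F|)
#'
#' The elliptic operator used by every smoothing term in the segmentation
#' PDEs. The gradient magnitude in the denominator is floored at `grad_floor`
#' to regularize flat regions; cells whose |grad F| falls below the floor
#' return exactly 0.
#'
#' @param field a `scalar_field` (or `level_set`).
#' @param grad_floor minimum gradient magnitude, in grid units. Default 1e-8.
#' @return a `scalar_field` holding kappa(F).
#' @examples
#' g <- grid_spec(c(64, 64))
#' sdf <- circle_sdf(g, center = c(32, 32), radius = 20)
#' # on the circle, kappa is about -1/r
#' @export
curvature <- function(field, grad_floor = 1e-8) {
  v <- field$values
  sp <- field$grid$spacing
  g <- grad_components(v, sp)
  nrm <- sqrt(Reduce(`+`, lapply(g, function(x) x * x)))
  flat <- nrm < grad_floor
  nrm_safe <- pmax(nrm, grad_floor)
  k <- 0
  for (a in seq_along(g)) {
    k <- k + central_diff(g[[a]] / nrm_safe, a, sp[a])
  }
  k[flat] <- 0
  scalar_field(k, field$grid)
}

# Conservative divergence-form diffusion step:
#   v <- v + dt * div( c grad v )
# with face coefficients taken as the arithmetic mean of the two adjacent
# cell coefficients and zero flux through the domain boundary. Used by the
# nonlinear input accumulator; written as a primitive so it can be tested
# for exact conservation.
diffuse_divform <- function(v, coef, spacing, dt) {
  upd <- 0
  for (a in seq_along(dim(v))) {
    h2 <- spacing[a]^2
    d <- dim(v)[a]
    # "plus" face between i and i+1: flux c_face * (v[i+1] - v[i]) / h^2
    vp <- axshift(v, a, 1L)
    cp <- 0.5 * (coef + axshift(coef, a, 1L))
    # replicate shift makes the boundary difference zero automatically
    # (v[i+1] == v[i] at the last cell), so no flux leaves the domain.
    fp <- cp * (vp - v) / h2
    vm <- axshift(v, a, -1L)
    cm <- 0.5 * (coef + axshift(coef, a, -1L))
    fm <- cm * (v - vm) / h2
    upd <- upd + (fp - fm)
  }
  v + dt * upd
}
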