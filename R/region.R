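#' Region-competition model specification
#'
#' Selects the open-loop, image-driven speed term G(phi, I): either the
#' global mean-alignment (Chan-Vese) competition, or the localized-statistics
#' variant in which the interior/exterior means are computed inside a
#' Euclidean ball around each narrowband cell. The localized model handles
#' images whose foreground/background statistics vary across the domain
#' (e.g. MRI soft tissue on an intensity ramp), where global means fail.
#'
#' @param kind `"global_means"` or `"localized_means"`.
#' @param r_loc ball radius in physical units (localized variant only), > 0.
#' @param lambda_smooth base curvature weight of the smoothing term; the
#'   default 0.1 is the conventional weight for unit-range intensities.
#' @return an object of class `region_model`.
#' @export
region_model <- function(kind = c("global_means", "localized_means"),
                         r_loc = NULL, lambda_smooth = 0.1) {
  kind <- match.arg(kind)
  if (kind == "localized_means") {
    if (is.null(r_loc) || !is.finite(r_loc) || r_loc <= 0)
      stop("localized_means requires r_loc > 0")
  }
  structure(list(kind = kind, r_loc = r_loc, lambda_smooth = lambda_smooth),
            class = "region_model")
}

#' Interior and exterior weighted intensity means
#'
#' The two region means weighted by the regularized Heaviside of phi:
#' `mu_in = sum(H I) / sum(H)`, `mu_out = sum((1-H) I) / sum((1-H))`
#' (cell sums times cell volume; the volume cancels in the ratio).
#'
#' @param I intensity `scalar_field`.
#' @param phi a `level_set` on the same grid.
#' @return named list `(mu_in, mu_out)`.
#' @export
region_means <- function(I, phi) {
  check_same_grid(I, phi)
  H <- heaviside_eps(phi$values, phi$eps)
  win <- sum(H)
  wout <- sum(1 - H)
  if (win <= .Machine$double.eps || wout <= .Machine$double.eps)
    stop("collapsed segmentation: interior or exterior has zero weight")
  list(mu_in = sum(H * I$values) / win,
       mu_out = sum((1 - H) * I$values) / wout)
}

#' Global mean-alignment (Chan-Vese) competition speed
#'
#' The data term of the open-loop region-competition PDE:
#' `G(x) = -(I - mu_in)^2 + (I - mu_out)^2`. Positive where the pixel looks
#' like the interior (expansion), negative where it looks like the exterior
#' (contraction). The curvature smoothing term is added by the evolution
#' loop, not here.
#'
#' @inheritParams region_means
#' @param means optional precomputed [region_means()] result.
#' @return a `scalar_field` of speeds.
#' @export
chan_vese_speed <- function(I, phi, means = NULL) {
  if (is.null(means)) means <- region_means(I, phi)
  g <- -(I$values - means$mu_in)^2 + (I$values - means$mu_out)^2
  scalar_field(g, I$grid)
}

#' Segmentation energy functional
#'
#' The region-competition energy whose gradient flow is the open-loop PDE:
#' half the Heaviside-weighted squared residuals against the two region
#' means, plus `lambda` times the total variation of the Heaviside label
#' (a regularized perimeter).
#'
#' @inheritParams region_means
#' @param lambda_smooth curvature/perimeter weight.
#' @param means optional precomputed means.
#' @return scalar energy value.
#' @export
energy <- function(I, phi, lambda_smooth, means = NULL) {
  if (is.null(means)) means <- region_means(I, phi)
  H <- heaviside_eps(phi$values, phi$eps)
  data_term <- 0.5 * sum(H * (I$values - means$mu_in)^2 +
                         (1 - H) * (I$values - means$mu_out)^2)
  per <- sum(grad_norm_arr(H, phi$grid$spacing))
  (data_term + lambda_smooth * per) * cell_volume(phi$grid)
}

# Precomputed ball footprint: integer offsets (one row per axis-offset
# combination) within Euclidean radius r_loc, in physical units.
ball_offsets <- function(grid, r_loc) {
  nmax <- pmax(1L, as.integer(floor(r_loc / grid$spacing)))
  ax <- lapply(seq_along(grid$shape), function(a) seq(-nmax[a], nmax[a]))
  off <- as.matrix(expand.grid(ax))
  phys <- sweep(off, 2, grid$spacing, `*`)
  off[rowSums(phys^2) <= r_loc^2, , drop = FALSE]
}

#' Localized region-competition speed
#'
#' For each narrowband cell x, interior/exterior means `mu_in(x)`,
#' `mu_out(x)` are Heaviside-weighted means of I restricted to the Euclidean
#' ball of radius `r_loc` around x; the returned speed is the delta-weighted
#' ball average of the pointwise competition residual
#' `-(I - mu_in(x))^2 + (I - mu_out(x))^2`, sharing the sign convention of
#' [chan_vese_speed()] (interior-matching pixels expand). The delta weight
#' restricts the residual to near-interface cells; normalizing by the ball
#' integral of the delta keeps |G| below the squared intensity range, the
#' bound the feedback gains are derived from. Cells whose ball has an empty
#' interior or exterior contribute 0; the speed is zero off the narrowband.
#'
#' @inheritParams region_means
#' @param r_loc ball radius in physical units, at least 2 cells.
#' @return a `scalar_field`, nonzero only on the narrowband of `phi`.
#' @export
localized_speed <- function(I, phi, r_loc) {
  check_same_grid(I, phi)
  if (r_loc < 2 * min(phi$grid$spacing)) stop("r_loc must be at least 2 cells")
  shp <- phi$grid$shape
  out <- array(0, shp)
  band <- narrowband(phi)
  if (length(band) == 0L) return(scalar_field(out, phi$grid))

  H <- heaviside_eps(phi$values, phi$eps)
  del <- delta_eps(phi$values, phi$eps)
  Iv <- I$values
  off <- ball_offsets(phi$grid, r_loc)
  bidx <- arrayInd(band, shp)

  nb <- length(band)
  s_h <- numeric(nb); s_hi <- numeric(nb)
  s_n <- numeric(nb); s_i <- numeric(nb)
  s_d0 <- numeric(nb); s_d1 <- numeric(nb)
  ndims <- length(shp)
  for (r in seq_len(nrow(off))) {
    pos <- bidx
    ok <- rep(TRUE, nb)
    for (a in seq_len(ndims)) {
      pa <- bidx[, a] + off[r, a]
      ok <- ok & pa >= 1L & pa <= shp[a]
      pos[, a] <- pa
    }
    if (!any(ok)) next
    lin <- pos[ok, 1L]
    mult <- 1L
    for (a in 2:ndims) {
      mult <- mult * shp[a - 1L]
      lin <- lin + (pos[ok, a] - 1L) * mult
    }
    hv <- H[lin]; iv <- Iv[lin]; dv <- del[lin]
    s_h[ok] <- s_h[ok] + hv
    s_hi[ok] <- s_hi[ok] + hv * iv
    s_n[ok] <- s_n[ok] + 1
    s_i[ok] <- s_i[ok] + iv
    s_d0[ok] <- s_d0[ok] + dv
    s_d1[ok] <- s_d1[ok] + dv * iv
  }
  s_b <- s_n - s_h
  s_bi <- s_i - s_hi
  valid <- s_h > 1e-8 & s_b > 1e-8 & s_d0 > 1e-8
  mu_in <- ifelse(valid, s_hi / pmax(s_h, 1e-300), 0)
  mu_out <- ifelse(valid, s_bi / pmax(s_b, 1e-300), 0)
  # delta-weighted ball sum of the residual, expanded in moments of I:
  #   sum dv * [-(I-mu_in)^2 + (I-mu_out)^2]
  #     = 2 (mu_in - mu_out) s_d1 - (mu_in^2 - mu_out^2) s_d0
  g <- ifelse(valid,
              (2 * (mu_in - mu_out) * s_d1 -
                 (mu_in^2 - mu_out^2) * s_d0) / pmax(s_d0, 1e-300),
              0)
  out[band] <- g
  scalar_field(out, phi$grid)
}

#' Image-derived speed bound
#'
#' Static pointwise and global upper bounds on |G| valid for any
#' segmentation state: both the global and localized competition speeds are
#' bounded by the squared intensity range, since each residual difference is
#' at most `(max I - min I)^2` for means within the image range. A static
#' bound (rather than a running max) fixes the input-magnitude threshold
#' before interaction starts.
#'
#' @param model a `region_model` (the bound holds for both kinds).
#' @param I intensity `scalar_field`.
#' @return object of class `speed_bound` with `pointwise` (`scalar_field`
#'   G_M(x)) and `global` (scalar, max of the pointwise bound).
#' @export
speed_bound <- function(model, I) {
  rng <- max(I$values) - min(I$values)
  gm <- scalar_field(array(rng^2, dim(I$values)), I$grid)
  structure(list(pointwise = gm, global = rng^2), class = "speed_bound")
}

#' Dispatch the open-loop competition speed for a model
#'
#' @param model a `region_model`.
#' @inheritParams region_means
#' @return a `scalar_field` G (without the curvature term).
#' @export
region_speed <- function(model, I, phi) {
  switch(model$kind,
         global_means = chan_vese_speed(I, phi),
         localized_means = localized_speed(I, phi, model$r_loc))
}
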