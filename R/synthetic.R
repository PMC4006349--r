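#' Two-ellipse "ventricle" phantom specification
#'
#' Geometry and noise parameters for the synthetic test image: two bright
#' ellipses joined by a thin bright bridge on a darker background, plus
#' additive Gaussian noise — a caricature of the lateral ventricles in a
#' brain scan. The ground-truth reference covers only the left ellipse,
#' which is exactly the configuration in which the purely image-driven
#' system leaks through the bridge and over-segments.
#'
#' @param shape image extents. Default `c(128, 128)`.
#' @param centers list of two length-2 centers (cell coords); defaults place
#'   the ellipses side by side.
#' @param axes list of two length-2 semi-axes (cells).
#' @param bridge_width bridge thickness in cells. Default 3.
#' @param fg,bg foreground / background intensities. Defaults 10 and 2.
#' @param noise_sd Gaussian noise standard deviation. Default 0.5.
#' @param seed RNG seed for the noise. Default 1.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128),
                         centers = list(c(40, 64), c(92, 64)),
                         axes = list(c(22, 15), c(20, 13)),
                         bridge_width = 3,
                         fg = 10, bg = 2, noise_sd = 0.5, seed = 1) {
  stopifnot(length(shape) == 2L, fg != bg, bridge_width >= 1)
  for (i in 1:2) {
    if (any(centers[[i]] - axes[[i]] < 1) ||
        any(centers[[i]] + axes[[i]] > shape))
      stop("invalid geometry: ellipse ", i, " extends out of bounds")
  }
  structure(list(shape = as.integer(shape), centers = centers, axes = axes,
                 bridge_width = bridge_width, fg = fg, bg = bg,
                 noise_sd = noise_sd, seed = seed),
            class = "phantom_spec")
}

#' Generate the two-ellipse phantom and its ground truth
#'
#' Rasterizes the two ellipses and the connecting bridge at the foreground
#' intensity over the background, adds seeded Gaussian noise, and builds the
#' reference labeling as the signed distance whose positive region is the
#' left ellipse only.
#'
#' @param spec a [phantom_spec()].
#' @param eps narrowband half-width for the returned reference. Default 1.5.
#' @return list `(I, psi)`: intensity `scalar_field` and reference
#'   `level_set`.
#' @export
make_phantom <- function(spec = phantom_spec(), eps = 1.5) {
  g <- grid_spec(spec$shape)
  X <- matrix(seq_len(spec$shape[1]), spec$shape[1], spec$shape[2])
  Y <- matrix(seq_len(spec$shape[2]), spec$shape[1], spec$shape[2],
              byrow = TRUE)
  inside <- function(c0, ax) {
    ((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 <= 1
  }
  e1 <- inside(spec$centers[[1]], spec$axes[[1]])
  e2 <- inside(spec$centers[[2]], spec$axes[[2]])
  # bridge: straight horizontal band between the two centers
  c1 <- spec$centers[[1]]; c2 <- spec$centers[[2]]
  half <- spec$bridge_width / 2
  ty <- c1[2] + (X - c1[1]) / (c2[1] - c1[1]) * (c2[2] - c1[2])
  br <- abs(Y - ty) <= half &
    X >= min(c1[1], c2[1]) & X <= max(c1[1], c2[1])
  fgmask <- e1 | e2 | br
  img <- array(spec$bg, spec$shape)
  img[fgmask] <- spec$fg
  if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(spec$seed)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), spec$shape)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  psi <- ellipse_sdf(g, spec$centers[[1]], spec$axes[[1]], eps = eps)
  list(I = scalar_field(img, g), psi = psi)
}

#' Gradient phantom where global means fail
#'
#' An elongated bright shape over a background with a linear intensity ramp.
#' The shape's contrast against its local background is constant, but its
#' placement and offset are chosen during generation so that the global
#' interior and exterior means nearly coincide (|mu_in - mu_out| < 5% of the
#' intensity range under the ground-truth labeling): the global
#' mean-alignment model has no usable signal while localized means separate
#' the shape everywhere.
#'
#' @param shape image extents. Default `c(96, 96)`.
#' @param center,axes ellipse center and semi-axes (cells); the default is a
#'   shape elongated along the ramp axis, so its interior spans a wide range
#'   of background levels.
#' @param ramp intensity range of the background ramp (low, high). Default
#'   `c(0, 10)` along the first axis.
#' @param mean_excess interior-vs-exterior global mean difference as a
#'   fraction of the ramp range; small and positive, so the dim end of the
#'   shape lies farther from the interior mean than from the exterior one
#'   and the global model actively misclassifies it. Default 0.04.
#' @param noise_sd Gaussian noise sd. Default 0.1.
#' @param seed RNG seed. Default 1.
#' @param eps narrowband half-width of the reference.
#' @return list `(I, psi)` as in [make_phantom()].
#' @export
make_gradient_phantom <- function(shape = c(96, 96), center = c(30, 48),
                                  axes = c(26, 10), ramp = c(0, 10),
                                  mean_excess = 0.04,
                                  noise_sd = 0.1, seed = 1, eps = 1.5) {
  stopifnot(length(shape) == 2L)
  if (any(center - axes < 1) || any(center + axes > shape))
    stop("invalid geometry: shape extends out of bounds")
  g <- grid_spec(shape)
  X <- matrix(seq_len(shape[1]), shape[1], shape[2])
  Y <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  bgr <- ramp[1] + (ramp[2] - ramp[1]) * (X - 1) / (shape[1] - 1)
  mask <- ((X - center[1]) / axes[1])^2 + ((Y - center[2]) / axes[2])^2 <= 1
  # offset chosen during generation so the global means nearly coincide
  # under the true labeling (interior mean a hair above the exterior one)
  offset <- mean(bgr[!mask]) - mean(bgr[mask]) +
    mean_excess * (ramp[2] - ramp[1])
  if (offset <= 0)
    stop("invalid geometry: shape must sit on the dim side of the ramp")
  img <- bgr
  img[mask] <- img[mask] + offset
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), shape)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  psi <- ellipse_sdf(g, center, axes, eps = eps)
  list(I = scalar_field(array(img, shape), g), psi = psi)
}

#' Simulated-user policy
#'
#' When and how the scripted user inspects the display and clicks: every
#' `interval` steps they look at the labeling error against their ideal
#' reference, click at up to `clicks_per_inspection` cells of largest
#' absolute error (ties broken by lexicographic cell index), and stop once
#' the largest error falls below `threshold` or `max_clicks` is exhausted.
#'
#' @param interval inspection interval in steps, >= 1. Default 5.
#' @param clicks_per_inspection clicks per look. Default 5.
#' @param threshold stop clicking when max |xi| is below this; the default
#'   0.8 means the user reacts only to boundary errors of two or more
#'   cells, not hairline misalignment.
#' @param max_clicks total click budget. Default 400.
#' @param warmup steps the user lets the automatic evolution run before the
#'   first inspection — they trust the expanding front and intervene once
#'   the boundary approaches their intended outline. Default 0.
#' @param watch_band clicks are placed only within this distance (grid
#'   units) of the displayed boundary: the user corrects the boundary where
#'   it is wrong, which is also where the narrowband dynamics can respond.
#'   Default 1.5 (the Heaviside transition band, where label changes are
#'   visible); `Inf` allows clicks anywhere.
#' @param seed RNG seed (used only by the optional random sampling mode).
#' @param mode `"max_error"` (default) or `"random_error"` (sample error
#'   cells at random instead of worst-first).
#' @return an object of class `user_policy`.
#' @export
user_policy <- function(interval = 5, clicks_per_inspection = 5,
                        threshold = 0.8, max_clicks = 400, warmup = 0,
                        watch_band = 1, seed = 1,
                        mode = c("max_error", "random_error")) {
  stopifnot(interval >= 1, warmup >= 0, watch_band > 0)
  structure(list(interval = as.integer(interval),
                 clicks_per_inspection = as.integer(clicks_per_inspection),
                 threshold = threshold, max_clicks = as.integer(max_clicks),
                 warmup = as.integer(warmup), watch_band = watch_band,
                 seed = seed, mode = match.arg(mode)),
            class = "user_policy")
}

#' Scripted simulated user
#'
#' Emits click events for the current display, following the vote rule
#' against the ground-truth reference: clicks go to the cells where the
#' labeling error |xi| is largest (the user acts "upon noticing" the worst
#' disagreement). When the previous inspection's error field is supplied,
#' only errors that have stalled or worsened since the last look are
#' eligible — the user trusts the automatic evolution while it is visibly
#' correcting an error, and intervenes where it is not. Deterministic for
#' fixed fields and policy.
#'
#' @param phi displayed `level_set`.
#' @param psi ground-truth reference `level_set`.
#' @param policy a [user_policy()].
#' @param t event time stamp to record.
#' @param budget remaining click budget (defaults to the policy maximum).
#' @param U optional `input_field`; when given, cells whose accumulated
#'   input magnitude already reaches `U$U_M` are skipped — the user does
#'   not keep marking a spot that is already fully marked.
#' @param prev_xi optional labeling-error array from the previous
#'   inspection; cells whose |error| decreased since then are skipped.
#' @return data.frame of click events (columns `t`, `x0`, `x1`\[, `x2`\],
#'   `u`, 0-based indices); zero rows when the user is satisfied. The
#'   current error array is attached as attribute `"xi"` for the caller to
#'   pass back at the next inspection.
#' @export
simulated_user <- function(phi, psi, policy, t = 0,
                           budget = policy$max_clicks, U = NULL,
                           prev_xi = NULL) {
  err <- label_error(phi, psi)
  xi_now <- err$xi$values
  a <- abs(xi_now)
  if (!is.null(U)) a[abs(U$field$values) >= U$U_M] <- 0
  if (is.finite(policy$watch_band))
    a[abs(phi$values) > policy$watch_band] <- 0
  if (!is.null(prev_xi)) a[abs(xi_now) < abs(prev_xi) - 1e-4] <- 0
  n <- min(policy$clicks_per_inspection, budget)
  ndims <- length(dim(a))
  empty <- stats::setNames(
    as.data.frame(matrix(numeric(0), 0, ndims + 2L)),
    c("t", paste0("x", seq_len(ndims) - 1L), "u"))
  attr(empty, "xi") <- xi_now
  if (n <= 0 || max(a) < policy$threshold) return(empty)
  cand <- which(a >= policy$threshold)
  if (policy$mode == "max_error") {
    ord <- order(-a[cand], cand)
    pick <- cand[ord[seq_len(min(n, length(cand)))]]
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(policy$seed + round(1000 * t))
    pick <- sample(cand, min(n, length(cand)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  idx <- arrayInd(pick, dim(a))
  u <- vote(sign(psi$values[pick]), sign(phi$values[pick]))
  out <- data.frame(t = t, idx - 1L, u = u)
  names(out) <- c("t", paste0("x", seq_len(ndims) - 1L), "u")
  out <- out[out$u != 0, , drop = FALSE]
  attr(out, "xi") <- xi_now
  out
}
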