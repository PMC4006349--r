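#' Accumulated user-input field
#'
#' Holds the control field U built up from signed clicks, together with its
#' saturation level `U_M` and the kernel scales: `sigma_x` (spatial Gaussian
#' width, physical units) and `sigma_I` (intensity-similarity scale). U
#' starts at zero everywhere; deposits add truncated kernel bumps and the
#' nonlinear diffusion step keeps |U| near or below `U_M` while smoothing.
#'
#' @param grid a `grid_spec`.
#' @param U_M saturation level, > 0.
#' @param sigma_x spatial kernel scale (physical units). Default 3 cells.
#' @param sigma_I intensity-similarity scale; default `"auto"` resolves to
#'   `sqrt(range(I)/2)` at first deposit so that `sigma_I^2` is half the
#'   intensity range.
#' @param gain impulse magnitude per click; default `U_M / 5` so that about
#'   five co-located clicks reach the saturating regime.
#' @param eps regularization width of the diffusion coefficient, applied
#'   to the dimensionless (U/U_M)^2 - 1; below 1 so the coefficient is
#'   exactly zero for small inputs. Default 0.5.
#' @return an object of class `input_field`.
#' @export
input_field <- function(grid, U_M, sigma_x = 3 * min(grid$spacing),
                        sigma_I = "auto", gain = U_M / 5, eps = 0.5) {
  stopifnot(U_M > 0, sigma_x > 0)
  structure(list(field = scalar_field(0, grid), U_M = U_M,
                 sigma_x = sigma_x, sigma_I = sigma_I, gain = gain,
                 eps = eps),
            class = "input_field")
}

#' Click vote rule
#'
#' The user's signed vote given the reference and displayed labels at the
#' clicked cell: +1 when the reference is interior but the display is
#' exterior, -1 in the opposite disagreement, 0 otherwise (including any
#' zero sign).
#'
#' @param ref_sign sign of the ideal reference psi at the click.
#' @param phi_sign sign of the displayed phi at the click.
#' @return -1, 0 or +1 (vectorized).
#' @export
vote <- function(ref_sign, phi_sign) {
  ifelse(ref_sign > 0 & phi_sign < 0, 1,
         ifelse(ref_sign < 0 & phi_sign > 0, -1, 0))
}

#' Click-spreading kernel
#'
#' Weight given to cell x for a click at x_k: the product of an
#' intensity-similarity factor `sigma_I^2 / (sigma_I^2 + |I(x) - I(x_k)|)`
#' and a spatial Gaussian `exp(-||x - x_k||^2 / (2 sigma_x^2))`. Distances
#' are physical; the intensity factor lets a click spread along similar
#' tissue rather than isotropically.
#'
#' @param dist physical distance(s) ||x - x_k||.
#' @param dI absolute intensity difference(s) |I(x) - I(x_k)|.
#' @param sigma_I,sigma_x kernel scales, > 0.
#' @return weights in (0, 1\].
#' @export
kernel_h0 <- function(dist, dI, sigma_I, sigma_x) {
  stopifnot(sigma_I > 0, sigma_x > 0)
  (sigma_I^2 / (sigma_I^2 + dI)) * exp(-dist^2 / (2 * sigma_x^2))
}

resolve_sigma_I <- function(U, I) {
  if (identical(U$sigma_I, "auto")) {
    rng <- max(I$values) - min(I$values)
    U$sigma_I <- sqrt(max(rng / 2, .Machine$double.eps))
  }
  U
}

#' Deposit one click into the input field
#'
#' Adds `u_k * gain * h0(. - x_k)` over the kernel footprint (truncated at
#' `3 sigma_x`). Zero votes deposit nothing; the Dirac impulse in time is
#' realized as an instantaneous additive update at the step containing t_k.
#'
#' @param U an `input_field`.
#' @param event one click: list/row with integer cell index vector `x`
#'   (1-based, length = grid dims) and sign `u` in \{-1, 0, +1\}.
#' @param I intensity `scalar_field` (for the similarity factor).
#' @return the updated `input_field`.
#' @export
deposit <- function(U, event, I) {
  u_k <- event$u
  if (!u_k %in% c(-1, 0, 1)) stop("click sign must be -1, 0 or +1")
  if (u_k == 0) return(U)
  grid <- U$field$grid
  x_k <- as.integer(round(event$x))
  if (length(x_k) != length(grid$shape) ||
      any(x_k < 1L) || any(x_k > grid$shape))
    stop("click location outside grid")
  U <- resolve_sigma_I(U, I)
  nmax <- pmax(1L, as.integer(ceiling(3 * U$sigma_x / grid$spacing)))
  lo <- pmax(1L, x_k - nmax)
  hi <- pmin(grid$shape, x_k + nmax)
  ax <- lapply(seq_along(grid$shape), function(a) lo[a]:hi[a])
  sub <- as.matrix(expand.grid(ax))
  d2 <- rowSums(sweep(sub, 2, x_k, `-`)^2 *
                  matrix(grid$spacing^2, nrow(sub), ncol(sub), byrow = TRUE))
  keep <- d2 <= (3 * U$sigma_x)^2
  sub <- sub[keep, , drop = FALSE]
  lin <- sub[, 1L]
  mult <- 1L
  for (a in seq_along(grid$shape)[-1L]) {
    mult <- mult * grid$shape[a - 1L]
    lin <- lin + (sub[, a] - 1L) * mult
  }
  I_k <- I$values[matrix(x_k, 1L)]
  w <- kernel_h0(sqrt(d2[keep]), abs(I$values[lin] - I_k),
                 U$sigma_I, U$sigma_x)
  v <- U$field$values
  v[lin] <- v[lin] + u_k * U$gain * w
  U$field <- with_values(U$field, v)
  U
}

#' One explicit step of the nonlinear input-diffusion PDE
#'
#' Advances `dU/dt = div( H_eps((U/U_M)^2 - 1) grad U )` by one explicit
#' divergence-form step with face-averaged coefficients and zero-flux
#' boundaries. The coefficient is negligible while |U| is well below `U_M`
#' (clicks accumulate essentially untouched) and ramps toward 1 as |U|
#' approaches and exceeds `U_M`, smearing out any excess — this is what
#' bounds the accumulated input without clipping it. The step conserves the
#' integral of U exactly up to round-off.
#'
#' @param U an `input_field`.
#' @param dt time step; must satisfy the diffusion stability bound
#'   `dt <= min(spacing)^2 / (2 * ndim)`.
#' @return the updated `input_field`.
#' @export
diffuse_U <- function(U, dt) {
  grid <- U$field$grid
  bound <- min(grid$spacing)^2 / (2 * length(grid$shape))
  if (dt > bound + 1e-12)
    stop("configuration error: dt = ", dt,
         " exceeds the diffusion stability bound ", bound)
  v <- U$field$values
  coef <- heaviside_eps((v / U$U_M)^2 - 1, U$eps)
  U$field <- with_values(U$field, diffuse_divform(v, coef, grid$spacing, dt))
  U
}

#' Read / write click streams
#'
#' CSV dialect with columns `t, x0, x1[, x2], u`: time, 0-based cell
#' indices, and the signed vote. The same format is produced by the
#' simulated user. Internally clicks use 1-based indices; the file format
#' is 0-based.
#'
#' @param path CSV file path.
#' @return `read_clicks`: a data.frame with columns `t`, `x0`, `x1`
#'   (optionally `x2`), `u`, sorted by `t`.
#' @export
read_clicks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "x0", "x1", "u")
  if (!all(need %in% names(df))) stop("click file must have columns t, x0, x1[, x2], u")
  if (!all(df$u %in% c(-1, 0, 1))) stop("click signs must be in {-1, 0, +1}")
  if (is.unsorted(df$t)) df <- df[order(df$t), , drop = FALSE]
  df
}

#' @rdname read_clicks
#' @param clicks data.frame of clicks (as from [simulated_user()] rounds).
#' @export
write_clicks <- function(clicks, path) {
  utils::write.csv(clicks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# convert a clicks data.frame row (0-based x columns) to the internal event
click_row_to_event <- function(row, ndims) {
  xcols <- paste0("x", seq_len(ndims) - 1L)
  list(x = as.integer(unlist(row[xcols])) + 1L, t = row$t, u = row$u)
}
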