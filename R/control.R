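#' Feedback-control configuration
#'
#' Gains of the stabilizing feedback law. The adaptive smoothing weight is
#' `lambda(t) = lambda0 + lambda1 * D` with D the labeling-error functional;
#' `rho` sets the margin in the input-magnitude threshold
#' `U_M = sqrt(G_M / rho + 1)`, the control magnitude above which the
#' feedback provably dominates the image term; `alpha` scales the input
#' inside the observer and defaults to `1 / U_M`.
#'
#' @param lambda0,lambda1 adaptive smoothing gains, > 0; defaults 0.1 and
#'   0.1, sized for unit-range intensities.
#' @param rho margin in (0, 1). Default 0.5.
#' @param U_M input saturation level; `"auto"` (default) derives it from a
#'   [speed_bound()] via [input_threshold()] at session setup.
#' @param alpha observer input scale; `"auto"` (default) resolves to `1/U_M`.
#' @param eps narrowband half-width shared with the level-set fields.
#' @return an object of class `control_config`.
#' @export
control_config <- function(lambda0 = 0.1, lambda1 = 0.1, rho = 0.5,
                           U_M = "auto", alpha = "auto", eps = 1.5) {
  stopifnot(lambda0 > 0, lambda1 > 0, eps > 0)
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)")
  if (is.numeric(U_M) && U_M <= 0) stop("U_M must be > 0")
  if (is.numeric(alpha) && alpha <= 0) stop("alpha must be > 0")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, rho = rho,
                 U_M = U_M, alpha = alpha, eps = eps),
            class = "control_config")
}

# Resolve "auto" entries of a control_config against an image-derived bound.
resolve_control <- function(cfg, bound) {
  if (identical(cfg$U_M, "auto")) cfg$U_M <- input_threshold(bound, cfg$rho)
  if (identical(cfg$alpha, "auto")) cfg$alpha <- 1 / cfg$U_M
  cfg
}

#' Pointwise and total labeling error against a reference
#'
#' `xi(x) = H_eps(phi) - H_eps(ref)` and `D = 0.5 * integral(xi^2)`
#' (cell sum times cell volume). D is the Lyapunov functional whose decrease
#' certifies convergence toward the reference labeling; |xi| <= 1 pointwise.
#'
#' @param phi a `level_set`.
#' @param ref reference `level_set` on the same grid (same role for the
#'   observer estimate).
#' @return object of class `error_state` with `xi` (`scalar_field`) and
#'   `D` (scalar >= 0).
#' @export
label_error <- function(phi, ref) {
  check_same_grid(phi, ref)
  xi <- heaviside_eps(phi$values, phi$eps) - heaviside_eps(ref$values, ref$eps)
  D <- 0.5 * sum(xi^2) * cell_volume(phi$grid)
  structure(list(xi = scalar_field(xi, phi$grid), D = D),
            class = "error_state")
}

#' Adaptive smoothing gain lambda(t) = lambda0 + lambda1 * D
#'
#' Increases smoothing when the labeling error is large, one of the two
#' sufficient conditions for boundedness of the error functional.
#'
#' @param cfg a `control_config`.
#' @param D labeling-error functional, >= 0.
#' @return the smoothing weight.
#' @export
adaptive_lambda <- function(cfg, D) {
  stopifnot(D >= 0)
  cfg$lambda0 + cfg$lambda1 * D
}

#' Input-magnitude threshold U_M
#'
#' The control magnitude `sqrt(G_M / rho + 1)` above which the squared-input
#' feedback term dominates the image-driven speed wherever the labeling
#' error is saturated; derived from the global speed bound.
#'
#' @param bound a [speed_bound()].
#' @param rho margin in (0, 1).
#' @return scalar threshold >= 1.
#' @export
input_threshold <- function(bound, rho) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie in (0, 1)")
  sqrt(bound$global / rho + 1)
}

#' Assembled closed-loop speed
#'
#' The bracketed term of the feedback-augmented PDE:
#' `G - xi_hat * U^2 + lambda * kappa(delta_eps(phi)^2 * xi_hat)`.
#' The squared-input term pushes phi toward the estimated reference wherever
#' the estimated labeling error is nonzero (the sign of U itself is
#' irrelevant here; direction comes from xi_hat); the composite-curvature
#' term smooths the error field. The open-loop curvature term cancels
#' algebraically against the control and is therefore not computed. With
#' `xi_hat = 0` the speed reduces exactly to G.
#'
#' @param G open-loop competition speed (`scalar_field`).
#' @param xi_hat estimated labeling-error `scalar_field`.
#' @param U accumulated input (`input_field` or `scalar_field`).
#' @param phi current `level_set`.
#' @param lam smoothing weight (from [adaptive_lambda()]).
#' @param grad_floor curvature regularization floor.
#' @return a `scalar_field` speed ready for [evolve_step()].
#' @export
closed_loop_speed <- function(G, xi_hat, U, phi, lam, grad_floor = 1e-8) {
  Uv <- if (inherits(U, "input_field")) U$field$values else U$values
  comp <- delta_eps(phi$values, phi$eps)^2 * xi_hat$values
  kap <- curvature(scalar_field(comp, phi$grid), grad_floor)
  scalar_field(G$values - xi_hat$values * Uv^2 + lam * kap$values, phi$grid)
}

#' Controlled run against a known reference
#'
#' The idealized setting of the stability analysis: the reference labeling
#' is known, the control field is held at the threshold magnitude
#' `U = U_M = sqrt(G_M / rho + 1)` everywhere, and the smoothing gain
#' adapts as `lambda(t) = lambda0 + lambda1 D(t)` with the true labeling
#' error. Under these gains the error functional D is bounded and decreases
#' whenever the large-error condition holds, driving the segmentation onto
#' the reference regardless of where the image term would take it.
#'
#' @param I intensity `scalar_field`.
#' @param phi0 initial `level_set`.
#' @param psi known reference `level_set`.
#' @param ctrl a [control_config()].
#' @param model a [region_model()] for the open-loop term.
#' @param steps number of explicit steps. Default 2000.
#' @param redist_every redistancing schedule. Default 5.
#' @param normalize rescale intensities to unit range first. Default TRUE.
#' @param cfl CFL safety factor. Default 0.45.
#' @return list with `phi` (final), `U_M`, and `trace` (data.frame per step:
#'   `D`, `lambda`, `descent` — whether the large-error condition held at
#'   the start of the step — and `redistanced`).
#' @export
run_known_reference <- function(I, phi0, psi, ctrl = control_config(),
                                model = region_model(), steps = 2000,
                                redist_every = 5, normalize = TRUE,
                                cfl = 0.45) {
  check_same_grid(I, phi0)
  check_same_grid(I, psi)
  if (normalize) I <- normalize_intensity(I)
  bound <- speed_bound(model, I)
  ctrl <- resolve_control(ctrl, bound)
  Uf <- scalar_field(array(ctrl$U_M, I$grid$shape), I$grid)
  phi <- redistance(phi0)
  tr <- data.frame(D = numeric(steps), lambda = numeric(steps),
                   descent = logical(steps), redistanced = logical(steps))
  for (s in seq_len(steps)) {
    err <- label_error(phi, psi)
    lam <- adaptive_lambda(ctrl, err$D)
    G <- region_speed(model, I, phi)
    sp <- closed_loop_speed(G, err$xi, Uf, phi, lam)
    tr$descent[s] <- descent_condition(phi, err$xi, ctrl$rho)
    dt <- cfl_dt(phi, sp, cfl)
    phi <- evolve_step(phi, sp, dt)
    if (s %% redist_every == 0L) {
      phi <- redistance(phi)
      tr$redistanced[s] <- TRUE
    }
    tr$D[s] <- label_error(phi, psi)$D
    tr$lambda[s] <- lam
  }
  list(phi = phi, U_M = ctrl$U_M, trace = tr)
}

#' Empirical Poincare constant (diagnostic)
#'
#' `r_hat = integral |delta_eps(phi)^2 xi| / integral |grad(delta_eps(phi)^2 xi)|`,
#' the constant of the L1 Poincare inequality evaluated numerically on the
#' current error configuration. It enters the convergence-rate analysis
#' only; reported as a diagnostic. Theory bounds it by half the domain
#' diameter; in practice it is on the order of the band width.
#'
#' @param phi a `level_set`.
#' @param xi labeling-error `scalar_field`.
#' @return scalar estimate.
#' @export
poincare_r <- function(phi, xi) {
  w <- delta_eps(phi$values, phi$eps)^2 * xi$values
  num <- sum(abs(w))
  den <- sum(grad_norm_arr(w, phi$grid$spacing))
  if (den <= .Machine$double.eps)
    stop("labeling error is zero on the narrowband; Poincare ratio undefined")
  num / den
}

#' Large-error descent condition
#'
#' TRUE when `rho * integral(delta^2 |xi|) <= integral(delta^2 xi^2)`, i.e.
#' the labeling error is large in the integral sense under which the
#' feedback guarantees monotone decrease of D. Used to gate monotonicity
#' assertions.
#'
#' @inheritParams poincare_r
#' @param rho margin in (0, 1).
#' @return logical.
#' @export
descent_condition <- function(phi, xi, rho) {
  d2 <- delta_eps(phi$values, phi$eps)^2
  rho * sum(d2 * abs(xi$values)) <= sum(d2 * xi$values^2)
}
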