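#' Observer state
#'
#' The auxiliary system that estimates the user's ideal boundary. The
#' estimate `psi_hat` starts equal to the initial phi and evolves driven by
#' the accumulated input U and two error fields: `xi_hat` (estimate vs.
#' displayed state) and `e_U` (estimate vs. input). Where the user never
#' clicks, the estimate simply follows phi; where input accumulates, the
#' estimate is increasingly driven toward the sign of U, and in turn pulls
#' phi along through the feedback coupling.
#'
#' @param phi0 initial `level_set`; `psi_hat` is initialized to a copy.
#' @return an object of class `observer_state` with elements `psi_hat`,
#'   `xi_hat`, `e_U` (the error fields are populated by
#'   [observer_errors()]).
#' @export
observer_init <- function(phi0) {
  structure(list(psi_hat = phi0,
                 xi_hat = scalar_field(0, phi0$grid),
                 e_U = scalar_field(0, phi0$grid)),
            class = "observer_state")
}

#' Observer error fields
#'
#' `xi_hat = H_eps(phi) - H_eps(psi_hat)` and
#' `e_U = H_eps(psi_hat) - H_eps(U)`, the Heaviside applied to the raw U
#' values with the same eps as the level sets. Both are bounded by 1 in
#' magnitude. Where U = 0 exactly, `H_eps(U) = 1/2`, so un-clicked regions
#' carry `e_U = +/- 1/2` wherever psi_hat is saturated — dynamically inert
#' there because e_U always enters multiplied by `(alpha U)^2`.
#'
#' @param phi displayed `level_set`.
#' @param psi_hat observer `level_set` on the same grid.
#' @param U an `input_field` (or `scalar_field`) on the same grid.
#' @return list `(xi_hat, e_U)` of `scalar_field`s.
#' @export
observer_errors <- function(phi, psi_hat, U) {
  check_same_grid(phi, psi_hat)
  Uf <- if (inherits(U, "input_field")) U$field else U
  check_same_grid(phi, Uf)
  xi_hat <- heaviside_eps(phi$values, phi$eps) -
    heaviside_eps(psi_hat$values, psi_hat$eps)
  e_U <- heaviside_eps(psi_hat$values, psi_hat$eps) -
    heaviside_eps(Uf$values, psi_hat$eps)
  list(xi_hat = scalar_field(xi_hat, phi$grid),
       e_U = scalar_field(e_U, phi$grid))
}

#' One explicit step of the observer PDE
#'
#' `psi_hat <- psi_hat + dt * delta_eps(psi_hat) * (xi_hat - e_U (alpha U)^2)`.
#' The delta prefactor confines the update to psi_hat's own narrowband. The
#' first term makes the estimate follow the displayed state; the second
#' drives it toward the accumulated input where |U| is large relative to
#' `1/alpha`.
#'
#' @param state an `observer_state` with current error fields (see
#'   [observer_errors()]).
#' @param U an `input_field`.
#' @param alpha input scale (typically `1/U_M`).
#' @param dt time step (same stability contract as [evolve_step()]).
#' @return the updated `observer_state`.
#' @export
observer_step <- function(state, U, alpha, dt) {
  Uv <- if (inherits(U, "input_field")) U$field$values else U$values
  rhs_field <- scalar_field(state$xi_hat$values -
                              state$e_U$values * (alpha * Uv)^2,
                            state$psi_hat$grid)
  state$psi_hat <- evolve_step(state$psi_hat, rhs_field, dt)
  state
}

#' Lyapunov functionals of the coupled estimate
#'
#' `F = integral( (alpha U)^2 e_U^2 / 2 )` measures disagreement between the
#' estimate and the accumulated input, weighted by input magnitude;
#' `D_hat = integral( xi_hat^2 / 2 )` measures disagreement between the
#' estimate and the displayed state; `V = F + D_hat` is the functional whose
#' decrease (once input stops) certifies stability of the coupled loop.
#'
#' @param state an `observer_state` with current error fields.
#' @param U an `input_field`.
#' @param alpha input scale.
#' @return named list `(F, D_hat, V)`.
#' @export
lyapunov_functionals <- function(state, U, alpha) {
  Uv <- if (inherits(U, "input_field")) U$field$values else U$values
  vol <- cell_volume(state$psi_hat$grid)
  Fv <- 0.5 * sum((alpha * Uv)^2 * state$e_U$values^2) * vol
  Dh <- 0.5 * sum(state$xi_hat$values^2) * vol
  list(F = Fv, D_hat = Dh, V = Fv + Dh)
}
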