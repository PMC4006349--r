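#' Session configuration
#'
#' Aggregates everything a segmentation run needs besides the image and the
#' initial contour: the region model, the control gains, the time-step
#' policy, the redistancing schedule and the termination tolerances.
#'
#' @param model a [region_model()].
#' @param control a [control_config()].
#' @param cfl CFL safety factor for the adaptive explicit step. Default 0.45.
#' @param dt_max cap on the time step. Default 1.
#' @param redist_every redistance phi and psi_hat every this many steps.
#'   Default 5.
#' @param max_steps step budget. Default 600.
#' @param steady_tol fraction of narrowband cells allowed to flip label in
#'   a step that still counts as quiescent (the default 1e-5 demands zero
#'   flips at ordinary band sizes).
#' @param steady_window consecutive quiescent, click-free steps required to
#'   declare steady state. Default 50.
#' @param sigma_x,sigma_I,click_gain input-kernel parameters forwarded to
#'   [input_field()] (`NULL` keeps that constructor's defaults).
#' @param normalize rescale intensities to unit range before the dynamics
#'   (default TRUE), so that the competition speed, the input threshold and
#'   the observer rates share one scale regardless of the image's native
#'   units. Labels, Dice and error functionals are unaffected.
#' @param seed RNG seed recorded for reproducibility. Default 1.
#' @return an object of class `session_config`.
#' @export
session_config <- function(model = region_model("global_means"),
                           control = control_config(),
                           cfl = 0.45, dt_max = 1, redist_every = 5,
                           max_steps = 600, steady_tol = 1e-5,
                           steady_window = 50, sigma_x = NULL,
                           sigma_I = NULL, click_gain = NULL,
                           normalize = TRUE, seed = 1) {
  stopifnot(steady_tol > 0, steady_window > 0, redist_every >= 1,
            cfl > 0, cfl <= 1, dt_max > 0)
  structure(list(model = model, control = control, cfl = cfl,
                 dt_max = dt_max, redist_every = as.integer(redist_every),
                 max_steps = as.integer(max_steps), steady_tol = steady_tol,
                 steady_window = as.integer(steady_window),
                 sigma_x = sigma_x, sigma_I = sigma_I,
                 click_gain = click_gain, normalize = isTRUE(normalize),
                 seed = as.integer(seed)),
            class = "session_config")
}

#' Rescale a field to unit range
#'
#' Affine map of the values onto \[0, 1\] (constant fields map to 0).
#'
#' @param I a `scalar_field`.
#' @return a `scalar_field` on the same grid.
#' @export
normalize_intensity <- function(I) {
  rng <- max(I$values) - min(I$values)
  if (rng <= .Machine$double.eps) return(with_values(I, 0))
  with_values(I, (I$values - min(I$values)) / rng)
}

new_input_for_session <- function(cfg, grid, U_M, eps) {
  args <- list(grid = grid, U_M = U_M, eps = eps)
  if (!is.null(cfg$sigma_x)) args$sigma_x <- cfg$sigma_x
  if (!is.null(cfg$sigma_I)) args$sigma_I <- cfg$sigma_I
  if (!is.null(cfg$click_gain)) args$gain <- cfg$click_gain
  do.call(input_field, args)
}

#' Run the coupled closed-loop segmentation session
#'
#' Orchestrates the three coupled fields per explicit step: ingest the
#' clicks that have come due (depositing their kernel bumps into U), update
#' the observer error fields, assemble the feedback speed
#' `G - xi_hat U^2 + lambda(t) kappa(delta^2 xi_hat)` with the adaptive
#' smoothing gain driven by the observer error functional, advance the
#' input-diffusion, observer and segmentation PDEs with one shared
#' CFL-conforming step, redistance on schedule, and append diagnostics.
#' Terminates at steady state (no pending clicks and the activity
#' functional quiet for `steady_window` consecutive steps) or at
#' `max_steps`.
#'
#' @param I intensity `scalar_field`.
#' @param phi0 initial `level_set` (redistanced internally).
#' @param clicks optional click stream data.frame (`t, x0, x1[, x2], u`,
#'   0-based indices) sorted by time, e.g. from [read_clicks()].
#' @param cfg a [session_config()].
#' @param psi optional ground-truth `level_set`; only recorded in
#'   diagnostics (D, Dice), never used in the dynamics.
#' @param user optional [user_policy()]; requires `psi`. When given, clicks
#'   are generated online by [simulated_user()] at inspection steps and the
#'   `clicks` argument is ignored.
#' @param init optional list with elements `psi_hat` and `U` to resume a
#'   session from a previous result's observer estimate and accumulated
#'   input (e.g. to continue after the click stream has ended).
#' @return list with `phi`, `psi_hat` (`level_set`s), `U` (`input_field`),
#'   `diagnostics` (one row per step), `clicks` (the ingested stream,
#'   including simulated ones), `steps`, `steady` (logical), and the
#'   resolved `control` gains.
#' @export
run_session <- function(I, phi0, clicks = NULL, cfg = session_config(),
                        psi = NULL, user = NULL, init = NULL) {
  grid <- I$grid
  check_same_grid(I, phi0)
  if (!is.null(user) && is.null(psi))
    stop("a simulated user requires the ground-truth psi")
  if (cfg$normalize) I <- normalize_intensity(I)
  bound <- speed_bound(cfg$model, I)
  ctrl <- resolve_control(cfg$control, bound)
  eps <- phi0$eps
  phi <- redistance(phi0)
  obs <- observer_init(phi)
  U <- new_input_for_session(cfg, grid, ctrl$U_M, eps)
  if (!is.null(init)) {
    if (!is.null(init$psi_hat)) obs$psi_hat <- init$psi_hat
    if (!is.null(init$U)) U <- init$U
  }

  stream <- if (is.null(clicks) || is.null(user)) clicks else NULL
  if (!is.null(stream) && nrow(stream) && is.unsorted(stream$t))
    stop("clicks must be sorted by time")
  next_click <- 1L
  clicks_used <- 0L
  user_prev_xi <- NULL
  user_looked <- FALSE
  taken <- list()
  actuated <- integer(0)
  diff_bound <- min(grid$spacing)^2 / (2 * length(grid$shape))
  t <- 0
  quiet <- 0L
  diag_rows <- vector("list", cfg$max_steps)
  prev_sign <- phi$values > 0
  steady <- FALSE
  steps <- 0L

  for (step in seq_len(cfg$max_steps)) {
    # --- 1. clicks due at this step -----------------------------------
    due <- NULL
    if (!is.null(user)) {
      if (step > user$warmup &&
          (step - 1L - user$warmup) %% user$interval == 0L &&
          clicks_used < user$max_clicks) {
        due <- simulated_user(phi, psi, user, t = t,
                              budget = user$max_clicks - clicks_used,
                              U = U, prev_xi = user_prev_xi)
        user_prev_xi <- attr(due, "xi")
        if (!user_looked) {  # first look only calibrates the comparison
          due <- due[0, , drop = FALSE]
          user_looked <- TRUE
        }
      }
    } else if (!is.null(stream)) {
      while (next_click <= nrow(stream) && stream$t[next_click] <= t) {
        due <- rbind(due, stream[next_click, , drop = FALSE])
        next_click <- next_click + 1L
      }
    }
    n_due <- if (is.null(due)) 0L else nrow(due)
    if (n_due > 0L) {
      for (r in seq_len(n_due)) {
        ev <- click_row_to_event(due[r, ], length(grid$shape))
        U <- deposit(U, ev, I)
        lin <- ev$x[1L]
        mult <- 1L
        for (a in seq_along(grid$shape)[-1L]) {
          mult <- mult * grid$shape[a - 1L]
          lin <- lin + (ev$x[a] - 1L) * mult
        }
        actuated <- union(actuated, lin)
      }
      clicks_used <- clicks_used + n_due
      taken[[length(taken) + 1L]] <- due
    }

    # --- 2. observer errors and assembled speeds ----------------------
    err <- observer_errors(phi, obs$psi_hat, U)
    obs$xi_hat <- err$xi_hat
    obs$e_U <- err$e_U
    lyap <- lyapunov_functionals(obs, U, ctrl$alpha)
    lam <- adaptive_lambda(ctrl, lyap$D_hat)
    G <- region_speed(cfg$model, I, phi)
    # feedback on top of the full open-loop flow (G + lambda kappa(phi)):
    # with no accumulated input the session reduces exactly to the
    # open-loop system, which also keeps the front smooth in noise.
    speed_phi <- closed_loop_speed(G, obs$xi_hat, U, phi, lam)
    speed_phi <- with_values(speed_phi, speed_phi$values +
                               cfg$model$lambda_smooth * curvature(phi)$values)
    rhs_psi <- scalar_field(obs$xi_hat$values -
                              obs$e_U$values *
                                (ctrl$alpha * U$field$values)^2, grid)

    # --- 3. shared stable time step -----------------------------------
    dt <- min(diff_bound, cfg$dt_max,
              cfl_dt(phi, speed_phi, cfg$cfl, cfg$dt_max),
              cfl_dt(obs$psi_hat, rhs_psi, cfg$cfl, cfg$dt_max))

    # --- 4. advance U, psi_hat, phi -----------------------------------
    U <- diffuse_U(U, dt)
    obs <- observer_step(obs, U, ctrl$alpha, dt)
    phi <- evolve_step(phi, speed_phi, dt)
    t <- t + dt
    steps <- step

    if (step %% cfg$redist_every == 0L) {
      phi <- try_redistance(phi)
      obs$psi_hat <- try_redistance(obs$psi_hat)
    }
    if (!any(phi$values > 0) || !any(phi$values < 0)) {
      diag <- do.call(rbind, diag_rows[seq_len(step - 1L)])
      stop(structure(class = c("contourctl_collapse", "error", "condition"),
                     list(message = paste0(
                            "segmentation collapsed (",
                            if (any(phi$values > 0)) "full" else "empty",
                            ") at step ", step),
                          call = sys.call(), diagnostics = diag)))
    }

    # --- 5. diagnostics -----------------------------------------------
    new_sign <- phi$values > 0
    recl <- sum(new_sign != prev_sign)
    prev_sign <- new_sign
    D <- if (!is.null(psi)) label_error(phi, psi)$D else NA_real_
    E <- energy(I, phi, cfg$model$lambda_smooth)
    diag_rows[[step]] <- data.frame(
      step = step, t = t, dt = dt, n_clicks = n_due, D = D,
      D_hat = lyap$D_hat, F = lyap$F, V = lyap$V, E = E, lambda = lam,
      actuated = length(actuated), reclassified = recl,
      max_abs_U = max(abs(U$field$values)))

    # --- 6. steady-state detection ------------------------------------
    # Steady state is judged on what the user sees: the inside/outside
    # labeling. The run is steady once no cell has flipped label for
    # `steady_window` consecutive steps and no click is pending. (The
    # Lyapunov functionals carry a redistancing sawtooth and a sub-cell
    # limit cycle, so they are reported but not used for termination.)
    pending <- if (!is.null(user)) {
      clicks_used < user$max_clicks && n_due > 0L
    } else if (!is.null(stream)) next_click <= nrow(stream) else FALSE
    flip_allow <- cfg$steady_tol * length(narrowband(phi))
    quiet <- if (recl <= flip_allow && !pending && n_due == 0L)
      quiet + 1L else 0L
    if (quiet >= cfg$steady_window) { steady <- TRUE; break }
  }

  diagnostics <- do.call(rbind, diag_rows[seq_len(steps)])
  rownames(diagnostics) <- NULL
  list(phi = phi, psi_hat = obs$psi_hat, U = U,
       diagnostics = diagnostics,
       clicks = if (length(taken)) do.call(rbind, taken) else NULL,
       actuated_cells = actuated, steps = steps, steady = steady,
       control = ctrl)
}

# redistance, tolerating a transiently one-signed field
try_redistance <- function(phi) {
  if (any(phi$values > 0) && any(phi$values < 0)) redistance(phi) else phi
}

#' Run the purely image-driven open-loop system
#'
#' The uncontrolled narrowband region-competition flow
#' `phi_t = delta_eps(phi) [G + lambda kappa(phi)]`: no user input, no
#' observer. This is the baseline whose failure (bleed-through into
#' adjacent structures with similar statistics) motivates the feedback.
#'
#' @inheritParams run_session
#' @param record_energy append the energy functional per step. Default TRUE.
#' @return list with `phi`, `diagnostics`, `steps`.
#' @export
run_open_loop <- function(I, phi0, cfg = session_config(), psi = NULL,
                          record_energy = TRUE) {
  grid <- I$grid
  check_same_grid(I, phi0)
  if (cfg$normalize) I <- normalize_intensity(I)
  phi <- redistance(phi0)
  diag_rows <- vector("list", cfg$max_steps)
  t <- 0
  steps <- 0L
  for (step in seq_len(cfg$max_steps)) {
    G <- region_speed(cfg$model, I, phi)
    kap <- curvature(phi)
    speed <- scalar_field(G$values + cfg$model$lambda_smooth * kap$values,
                          grid)
    dt <- cfl_dt(phi, speed, cfg$cfl, cfg$dt_max)
    phi <- evolve_step(phi, speed, dt)
    t <- t + dt
    steps <- step
    redist <- step %% cfg$redist_every == 0L
    if (redist) phi <- try_redistance(phi)
    if (!any(phi$values > 0) || !any(phi$values < 0))
      stop("segmentation collapsed at step ", step)
    E <- if (record_energy) energy(I, phi, cfg$model$lambda_smooth) else NA_real_
    D <- if (!is.null(psi)) label_error(phi, psi)$D else NA_real_
    diag_rows[[step]] <- data.frame(step = step, t = t, dt = dt, E = E,
                                    D = D, redistanced = redist)
  }
  diagnostics <- do.call(rbind, diag_rows[seq_len(steps)])
  rownames(diagnostics) <- NULL
  list(phi = phi, diagnostics = diagnostics, steps = steps)
}

#' Interaction-effort summary
#'
#' Totals and per-input-round pairs of (newly actuated, reclassified)
#' voxels: actuated voxels are the distinct cells the user clicked (set
#' semantics); reclassified voxels are cells whose inside/outside label
#' flipped in response to a round of input, counted until the next round.
#' When a reference is supplied, the actuated total is also expressed as a
#' percentage of the reference boundary-cell count — the effort a fully
#' manual tracing would take.
#'
#' @param result a [run_session()] result (uses its `diagnostics` and
#'   `actuated_cells`).
#' @param ref optional ground-truth `level_set` for the boundary-count
#'   percentage.
#' @return list with `total_actuated`, `total_reclassified`, `rounds`
#'   (data.frame `newly_actuated`, `reclassified`), and
#'   `actuated_pct_of_boundary` (NA without `ref`).
#' @export
effort_metrics <- function(result, ref = NULL) {
  d <- result$diagnostics
  total_act <- length(result$actuated_cells)
  total_recl <- sum(d$reclassified)
  rsteps <- which(d$n_clicks > 0L)
  rounds <- if (length(rsteps)) {
    ends <- c(rsteps[-1L] - 1L, nrow(d))
    prev_act <- c(0L, d$actuated[rsteps[-length(rsteps)]])
    data.frame(
      step = rsteps,
      newly_actuated = d$actuated[rsteps] - prev_act,
      reclassified = vapply(seq_along(rsteps), function(i)
        sum(d$reclassified[rsteps[i]:ends[i]]), numeric(1)))
  } else {
    data.frame(step = integer(0), newly_actuated = integer(0),
               reclassified = numeric(0))
  }
  pct <- NA_real_
  if (!is.null(ref)) {
    nb <- length(interface_cells(ref, interior_only = TRUE))
    pct <- 100 * total_act / nb
  }
  list(total_actuated = total_act, total_reclassified = total_recl,
       rounds = rounds, actuated_pct_of_boundary = pct)
}
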