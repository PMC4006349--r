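test_that("sessions are deterministic and reduce to the open loop without input", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- circle_sdf(g, c(30, 48), 7)
  cfg <- session_config(max_steps = 60)
  a <- run_session(ph$I, phi0, cfg = cfg)
  b <- run_session(ph$I, phi0, cfg = cfg)
  expect_identical(a$phi$values, b$phi$values)
  expect_identical(a$diagnostics, b$diagnostics)
  # without input U stays zero and the observer tracks phi
  expect_equal(max(abs(a$U$field$values)), 0)
  expect_lt(tail(a$diagnostics$D_hat, 1), 2)
  # the session front is the open-loop front damped by the observer
  # coupling: it grows inside the open-loop region, never elsewhere
  ol <- run_open_loop(ph$I, phi0, cfg)
  sess_in <- interior_mask(a$phi)
  expect_gt(sum(sess_in & interior_mask(ol$phi)) / sum(sess_in), 0.97)
  expect_gt(sum(sess_in), sum(interior_mask(phi0)))
})

test_that("the first session step without input equals the open-loop speed exactly", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- redistance(circle_sdf(g, c(30, 48), 7))
  In <- normalize_intensity(ph$I)
  model <- region_model("global_means")
  # assembled closed-loop speed with xi_hat = 0 plus the open-loop smoothing
  G <- chan_vese_speed(In, phi0)
  sp_cl <- closed_loop_speed(G, scalar_field(0, g), scalar_field(0, g),
                             phi0, lam = 0.5)
  sp_cl <- with_values(sp_cl, sp_cl$values +
                         model$lambda_smooth * curvature(phi0)$values)
  sp_ol <- with_values(G, G$values + model$lambda_smooth * curvature(phi0)$values)
  expect_equal(sp_cl$values, sp_ol$values)
})

test_that("clicks from a stream are ingested at their due times", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- circle_sdf(g, c(30, 48), 7)
  clicks <- data.frame(t = c(0, 0.5, 3), x0 = c(29, 30, 31),
                       x1 = c(47, 47, 47), u = c(1, 1, -1))
  cfg <- session_config(max_steps = 50)
  res <- run_session(ph$I, phi0, clicks = clicks, cfg = cfg)
  expect_equal(sum(res$diagnostics$n_clicks), 3)
  expect_gt(max(abs(res$U$field$values)), 0)
  expect_equal(length(res$actuated_cells), 3)
  # unsorted streams are rejected
  expect_error(run_session(ph$I, phi0, clicks = clicks[c(3, 1, 2), ],
                           cfg = cfg), "sorted")
})

test_that("effort metrics use set semantics and count label flips per round", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- circle_sdf(g, c(30, 48), 7)
  # two clicks at the same cell and one elsewhere
  clicks <- data.frame(t = c(0, 0, 2), x0 = c(29, 29, 40),
                       x1 = c(47, 47, 50), u = c(1, 1, 1))
  cfg <- session_config(max_steps = 40)
  res <- run_session(ph$I, phi0, clicks = clicks, cfg = cfg)
  em <- effort_metrics(res, ref = ph$psi)
  expect_equal(em$total_actuated, 2)  # distinct cells only
  expect_equal(nrow(em$rounds), 2)
  expect_equal(sum(em$rounds$newly_actuated), 2)
  # reclassified equals the brute-force sign-flip count summed over steps
  expect_equal(em$total_reclassified, sum(res$diagnostics$reclassified))
  expect_true(is.finite(em$actuated_pct_of_boundary))
  # no clicks -> zero effort
  res0 <- run_session(ph$I, phi0, cfg = session_config(max_steps = 10))
  em0 <- effort_metrics(res0)
  expect_equal(em0$total_actuated, 0)
  expect_equal(nrow(em0$rounds), 0)
})

test_that("per-step reclassification is bounded by the narrowband size", {
  ph <- small_phantom()
  phi0 <- circle_sdf(ph$I$grid, c(30, 48), 7)
  cfg <- session_config(max_steps = 150)
  res <- run_session(ph$I, phi0, cfg = cfg, psi = ph$psi, user = user_policy())
  nb_size <- length(narrowband(res$phi))
  # continuity: no step flips more cells than a band's worth
  expect_true(all(res$diagnostics$reclassified <= 3 * nb_size))
})

test_that("a collapsing segmentation aborts with diagnostics attached", {
  g <- tiny_grid(32)
  # a user voting the entire seed away drives phi to extinction
  phi0 <- circle_sdf(g, c(16, 16), 5)
  I <- scalar_field(5, g)
  clicks <- data.frame(t = rep(0:19, each = 2),
                       x0 = rep(c(15, 16), 20), x1 = rep(c(15, 16), 20),
                       u = -1)
  cfg <- session_config(max_steps = 600, steady_window = 1e6)
  err <- tryCatch(run_session(I, phi0, clicks = clicks, cfg = cfg),
                  condition = identity)
  expect_s3_class(err, "contourctl_collapse")
  expect_true(!is.null(err$diagnostics))
})

test_that("a session resumes from a previous observer estimate and input field", {
  ph <- small_phantom()
  phi0 <- circle_sdf(ph$I$grid, c(30, 48), 7)
  clicks <- data.frame(t = 0, x0 = 29, x1 = 47, u = 1)
  cfg <- session_config(max_steps = 30)
  a <- run_session(ph$I, phi0, clicks = clicks, cfg = cfg)
  b <- run_session(ph$I, a$phi, cfg = cfg,
                   init = list(psi_hat = a$psi_hat, U = a$U))
  # the accumulated input carries over and keeps diffusing, not resetting
  expect_gt(max(abs(b$U$field$values)), 0)
  expect_equal(sum(b$U$field$values), sum(a$U$field$values),
               tolerance = 1e-9)
})

test_that("steady state is detected on a quiescent run and persists", {
  ph <- small_phantom(noise_sd = 0)
  # seed at the open-loop equilibrium (the full bright region): the system
  # starts quiescent, so detection must fire shortly after the window fills
  union_mask <- ph$I$values > 6
  phi0 <- redistance(level_set(ifelse(union_mask, 1, -1), ph$I$grid))
  cfg <- session_config(max_steps = 1500)
  res <- run_session(ph$I, phi0, cfg = cfg)
  expect_true(res$steady)
  expect_lt(res$steps, 500)
  # non-degradation: continuing well past detection barely moves the label
  cfg2 <- session_config(max_steps = res$steps + 500, steady_window = 1e6)
  res2 <- run_session(ph$I, phi0, cfg = cfg2)
  d <- dice_coefficient(res$phi, res2$phi)
  expect_gt(d, 0.995)
})
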