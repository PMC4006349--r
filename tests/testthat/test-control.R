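test_that("label error is the Heaviside difference with D = half its square integral", {
  g <- tiny_grid(48)
  phi <- circle_sdf(g, c(24, 24), 10)
  same <- label_error(phi, phi)
  expect_equal(max(abs(same$xi$values)), 0)
  expect_equal(same$D, 0)
  ref <- circle_sdf(g, c(24, 24), 10)
  patch <- ref$values
  patch[10:14, 35:40] <- -5
  ref2 <- with_values(ref, patch)
  expect_true(all(abs(label_error(phi, ref2)$xi$values) <= 1 + 1e-12))
  # antisymmetry
  e12 <- label_error(phi, ref2)
  e21 <- label_error(ref2, phi)
  expect_equal(e12$xi$values, -e21$xi$values)
  expect_equal(e12$D, e21$D)
  # D recomputable from xi
  expect_equal(e12$D, 0.5 * sum(e12$xi$values^2) * cell_volume(g))
})

test_that("saturated-patch label error integrates to half the patch volume", {
  g <- tiny_grid(48)
  base <- circle_sdf(g, c(24, 24), 10)
  # construct phi/ref saturated and opposite on an exact 30-cell patch
  phi_v <- base$values
  ref_v <- base$values
  phi_v[40:44, 5:10] <- 5
  ref_v[40:44, 5:10] <- -5
  err <- label_error(level_set(phi_v, g), level_set(ref_v, g))
  expect_equal(err$D, 30 / 2)
})

test_that("adaptive lambda and the input threshold follow their closed forms", {
  cfg <- control_config(lambda0 = 1, lambda1 = 2)
  expect_equal(adaptive_lambda(cfg, 3), 7)
  expect_equal(adaptive_lambda(cfg, 0), 1)
  D <- seq(0, 10, by = 0.5)
  expect_true(all(diff(vapply(D, adaptive_lambda, 1, cfg = cfg)) >= 0))
  expect_equal(input_threshold(list(global = 3), 0.5), sqrt(7))
  expect_equal(input_threshold(list(global = 0), 0.5), 1)
  expect_equal(input_threshold(list(global = 99), 0.99), 10.04987562,
               tolerance = 1e-8)
  expect_error(input_threshold(list(global = 1), 1.5), "rho")
})

test_that("closed-loop speed reduces to G without error and applies -xi U^2", {
  g <- tiny_grid(32)
  phi <- circle_sdf(g, c(16, 16), 8)
  G <- scalar_field(array(rnorm(32 * 32), c(32, 32)), g)
  zero <- scalar_field(0, g)
  sp <- closed_loop_speed(G, zero, scalar_field(2, g), phi, lam = 3)
  expect_equal(sp$values, G$values)
  # pointwise feedback sign: xi = 1, U = 2, lambda = 0, G = 0 -> -4
  one <- scalar_field(1, g)
  sp2 <- closed_loop_speed(scalar_field(0, g), one, scalar_field(2, g), phi, 0)
  expect_equal(sp2$values, array(-4, c(32, 32)))
  sp3 <- closed_loop_speed(scalar_field(0, g), with_values(one, -1),
                           scalar_field(2, g), phi, 0)
  expect_equal(sp3$values, array(4, c(32, 32)))
})

test_that("empirical Poincare ratio is scale-free and bounded by the domain", {
  g <- grid_spec(c(64, 64))
  phi <- circle_sdf(g, c(32, 32), 14)
  xi <- scalar_field(delta_eps(phi$values, phi$eps) * 1.5, g)  # band-supported
  r1 <- poincare_r(phi, xi)
  expect_lt(r1, 0.5 * sqrt(2) * 64)
  expect_lt(r1, 5)  # on the order of the band width
  r2 <- poincare_r(phi, with_values(xi, 7 * xi$values))
  expect_equal(r1, r2)
  expect_error(poincare_r(phi, scalar_field(0, g)), "zero|undefined")
})

test_that("the large-error descent condition matches its integral definition", {
  g <- tiny_grid(32)
  phi <- circle_sdf(g, c(16, 16), 8)
  sat <- scalar_field(ifelse(abs(phi$values) < 3, 1, 0), g)
  expect_true(descent_condition(phi, sat, rho = 0.9))
  tiny <- with_values(sat, 0.1 * sat$values)
  expect_false(descent_condition(phi, tiny, rho = 0.5))
  expect_true(descent_condition(phi, scalar_field(0, g), rho = 0.5))
})

test_that("known-reference control bounds and shrinks the labeling error", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- circle_sdf(g, c(38, 56), 12)
  d0 <- dice_coefficient(phi0, ph$psi)
  expect_lt(d0, 0.75)
  res <- run_known_reference(ph$I, phi0, ph$psi, steps = 900)
  tr <- res$trace
  # D bounded: never exceeds twice its starting value
  expect_lt(max(tr$D), 2 * tr$D[1])
  # monotone decrease where the descent condition holds (non-redistancing steps)
  ok <- tr$descent[-nrow(tr)] & !tr$redistanced[-nrow(tr)] & !tr$redistanced[-1]
  dD <- diff(tr$D)
  expect_true(all(dD[ok] <= 1e-4 * tr$D[-nrow(tr)][ok] + 1e-9))
  expect_gt(dice_coefficient(res$phi, ph$psi), 0.98)
})
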