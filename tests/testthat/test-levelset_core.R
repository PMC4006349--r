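test_that("regularized Heaviside matches its three-branch definition", {
  expect_equal(heaviside_eps(3, 2), 1)
  expect_equal(heaviside_eps(-3, 2), 0)
  expect_equal(heaviside_eps(0, 2), 0.5)
  expect_equal(heaviside_eps(1, 2), 0.75 + 1 / (2 * pi))
  # symmetry and monotonicity over the band
  x <- seq(-4, 4, by = 0.01)
  expect_equal(heaviside_eps(x, 2) + heaviside_eps(-x, 2), rep(1, length(x)))
  expect_true(all(diff(heaviside_eps(x, 2)) >= -1e-12))
  expect_error(heaviside_eps(1, 0), "eps")
})

test_that("regularized delta is the Heaviside derivative with band support", {
  expect_equal(delta_eps(0, 2), 0.5)
  expect_equal(delta_eps(3, 2), 0)
  expect_equal(delta_eps(-2.01, 2), 0)
  expect_equal(delta_eps(1, 2), 0.25)
  # centered finite difference of H matches delta to 1e-3
  eps <- 1.5
  x <- seq(-2 * eps, 2 * eps, length.out = 301)
  h <- 1e-4
  fd <- (heaviside_eps(x + h, eps) - heaviside_eps(x - h, eps)) / (2 * h)
  expect_lt(max(abs(fd - delta_eps(x, eps))), 1e-3)
})

test_that("curvature recovers -1/r on circles and 0 on flat fields", {
  g <- grid_spec(c(128, 128))
  rho <- sqrt(outer((seq_len(128) - 64)^2, (seq_len(128) - 64)^2, `+`))
  for (r in c(20, 35)) {
    phi <- circle_sdf(g, c(64, 64), r)
    k <- curvature(phi)
    band <- narrowband(phi)
    # pointwise analytic curvature of the distance cone is -1/rho
    expect_lt(max(abs(k$values[band] * rho[band] + 1)), 0.05)
  }
  ramp <- scalar_field(outer(seq_len(32), rep(1, 32)) * 0.7 + 2, tiny_grid())
  expect_equal(max(abs(curvature(ramp)$values[3:30, 3:30])), 0)
  flat <- scalar_field(5, tiny_grid())
  expect_equal(max(abs(curvature(flat)$values)), 0)
})

test_that("redistancing restores a signed distance and preserves the interface", {
  g <- grid_spec(c(96, 96))
  phi_true <- circle_sdf(g, c(48, 48), 20)
  scaled <- with_values(phi_true, 2 * phi_true$values)
  rd <- redistance(scaled)
  band <- narrowband(rd)
  # distance values match the analytic circle distance on the band
  expect_lt(max(abs(rd$values[band] - phi_true$values[band])), 0.15)
  # gradient magnitude ~ 1 on the band
  gn <- gradient_norm(rd)
  expect_true(all(gn$values[band] > 0.8 & gn$values[band] < 1.2))
  # idempotence to 0.1 cells
  rd2 <- redistance(rd)
  expect_lt(max(abs(rd2$values[band] - rd$values[band])), 0.1)
  # sign pattern preserved away from the interface
  far <- abs(phi_true$values) > 2
  expect_true(all(sign(rd$values[far]) == sign(phi_true$values[far])))
  expect_error(redistance(with_values(phi_true, abs(phi_true$values) + 1)),
               "uniformly signed|empty/full")
})

test_that("redistancing gives each of two disjoint circles its own distance field", {
  g <- grid_spec(c(80, 80))
  a <- circle_sdf(g, c(24, 24), 10)
  b <- circle_sdf(g, c(56, 56), 8)
  phi <- level_set(pmax(a$values, b$values), g)
  rd <- redistance(phi)
  bd <- brute_distance(phi$values)
  band <- narrowband(rd)
  expect_lt(max(abs(abs(rd$values[band]) - bd[band])), 1)
})

test_that("narrowband is exactly the |phi| <= eps cell set", {
  g <- grid_spec(c(64, 64))
  phi <- circle_sdf(g, c(32, 32), 15)
  nb <- narrowband(phi)
  expect_identical(nb, which(abs(phi$values) <= phi$eps))
  # brute-force annulus check against the analytic distance
  r <- sqrt(outer((seq_len(64) - 32)^2, (seq_len(64) - 32)^2, `+`))
  expect_identical(nb, which(abs(15 - r) <= 1.5))
  expect_length(narrowband(level_set(array(10, c(64, 64)), g)), 0)
  wide <- level_set(phi$values, g, eps = 1e4)
  expect_length(narrowband(wide), 64 * 64)
})

test_that("evolve_step acts only on the narrowband and is linear in dt", {
  g <- grid_spec(c(64, 64))
  phi <- circle_sdf(g, c(32, 32), 12)
  zero <- scalar_field(0, g)
  expect_identical(evolve_step(phi, zero, 0.1)$values, phi$values)
  cs <- scalar_field(0.5, g)
  out <- abs(phi$values) > phi$eps
  stepped <- evolve_step(phi, cs, 0.5)
  expect_identical(stepped$values[out], phi$values[out])  # containment exact
  # positive speed inflates the zero level set
  grown <- phi
  for (k in 1:40) grown <- evolve_step(redistance(grown), cs, 0.5)
  expect_gt(sum(interior_mask(grown)), sum(interior_mask(phi)))
  # forward then backward step restores phi up to the O(dt^2) nonlinearity
  back <- evolve_step(evolve_step(phi, cs, 1e-3), cs, -1e-3)
  expect_lt(max(abs(back$values - phi$values)), 1e-5)
  expect_error(evolve_step(phi, scalar_field(100, g), 1), "stability")
})

test_that("cfl_dt respects the per-step displacement bound", {
  g <- grid_spec(c(64, 64))
  phi <- circle_sdf(g, c(32, 32), 12)
  sp <- scalar_field(3, g)
  dt <- cfl_dt(phi, sp)
  rhs <- delta_eps(phi$values, phi$eps) * sp$values
  expect_lte(dt * max(abs(rhs)), 0.45 * 1 + 1e-12)
  expect_equal(cfl_dt(phi, scalar_field(0, g)), 1)
})

test_that("anisotropic spacing is honored by the difference operators", {
  g <- grid_spec(c(64, 64), spacing = c(0.5, 2))
  # tilted plane: central differences are exact for linear fields
  x <- (seq_len(64)) * 0.5
  y <- (seq_len(64)) * 2
  plane <- outer(0.6 * x, 0.8 * y, `+`)
  gn <- gradient_norm(scalar_field(plane, g))
  expect_equal(max(abs(gn$values[3:62, 3:62] - 1)), 0, tolerance = 1e-10)
  # redistancing a stretched circle recovers physical distances
  r <- sqrt(outer(((seq_len(64) - 32) * 0.5)^2, ((seq_len(64) - 32) * 2)^2, `+`))
  phi <- level_set(2 * (20 - r), g)
  rd <- redistance(phi)
  band <- which(abs(20 - r) <= 1.5 & r > 5)
  expect_lt(max(abs(rd$values[band] - (20 - r[band]))), 1)
})
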