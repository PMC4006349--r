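test_that("region means are Heaviside-weighted image averages", {
  g <- tiny_grid(48)
  phi <- circle_sdf(g, c(24, 24), 10)
  cs <- scalar_field(7, g)
  m <- region_means(cs, phi)
  expect_equal(m$mu_in, 7)
  expect_equal(m$mu_out, 7)
  # two-level image split by the contour, eps much smaller than regions
  I <- with_values(cs, ifelse(phi$values > 0, 10, 2))
  m2 <- region_means(I, phi)
  # band cells mix the two plateaus; tolerance set by the band fraction
  expect_equal(m2$mu_in, 10, tolerance = 0.1)
  expect_equal(m2$mu_out, 2, tolerance = 0.1)
  # brute-force masked average against an exact disc interior
  H <- heaviside_eps(phi$values, phi$eps)
  set.seed(4)
  Ir <- with_values(cs, array(runif(48 * 48, 0, 5), c(48, 48)))
  m3 <- region_means(Ir, phi)
  expect_equal(m3$mu_in, sum(H * Ir$values) / sum(H))
  expect_error(region_means(cs, level_set(array(10, c(48, 48)), g)),
               "collapsed")
})

test_that("mean-alignment speed has the region-competition sign structure", {
  g <- tiny_grid(48)
  phi <- circle_sdf(g, c(24, 24), 10)
  I <- scalar_field(ifelse(phi$values > 0, 10, 2), g)
  m <- region_means(I, phi)
  sp <- chan_vese_speed(I, phi, means = m)
  gap2 <- (m$mu_in - m$mu_out)^2
  probe <- function(val) -(val - m$mu_in)^2 + (val - m$mu_out)^2
  expect_equal(probe(m$mu_in), gap2)
  expect_equal(probe((m$mu_in + m$mu_out) / 2), 0)
  expect_equal(probe(m$mu_out), -gap2)
  # field agrees with the formula
  expect_equal(sp$values,
               -(I$values - m$mu_in)^2 + (I$values - m$mu_out)^2)
  # antisymmetry: negate phi and swap means -> negated speed
  phin <- with_values(phi, -phi$values)
  spn <- chan_vese_speed(I, phin,
                         means = list(mu_in = m$mu_out, mu_out = m$mu_in))
  expect_equal(spn$values, -sp$values)
})

test_that("energy vanishes on a perfect partition and recovers the perimeter", {
  g <- grid_spec(c(96, 96))
  phi <- circle_sdf(g, c(48, 48), 25)
  I <- scalar_field(ifelse(phi$values > 0, 10, 2), g)
  # the aligned partition's data energy is far below a misaligned one's
  e_good <- energy(I, phi, lambda_smooth = 0)
  e_bad <- energy(I, circle_sdf(g, c(70, 70), 25), lambda_smooth = 0)
  expect_lt(e_good / e_bad, 0.05)
  # lambda term ~ lambda * 2 pi R for a circle
  Iconst <- scalar_field(5, g)
  e_per <- energy(Iconst, phi, lambda_smooth = 1)
  expect_equal(e_per, 2 * pi * 25, tolerance = 0.05)
})

test_that("localized speed reduces to the global residual structure for huge balls", {
  g <- tiny_grid(32)
  set.seed(7)
  I <- scalar_field(array(runif(32 * 32, 0, 1), c(32, 32)), g)
  phi <- circle_sdf(g, c(16, 16), 8)
  ls <- localized_speed(I, phi, r_loc = 100)
  oracle <- brute_localized_speed(I, phi, 100)
  expect_equal(ls$values, oracle, tolerance = 1e-10)
  # and against the oracle at a genuinely local radius
  ls2 <- localized_speed(I, phi, r_loc = 5)
  oracle2 <- brute_localized_speed(I, phi, 5)
  expect_equal(ls2$values, oracle2, tolerance = 1e-10)
  # constant image -> zero speed
  expect_equal(max(abs(localized_speed(scalar_field(3, g), phi, 6)$values)), 0)
  expect_error(localized_speed(I, phi, 1), "2 cells")
})

test_that("localized speed corrects a misplaced contour on a ramp background", {
  gp <- make_gradient_phantom(noise_sd = 0)
  In <- normalize_intensity(gp$I)
  g <- In$grid
  shrunken <- redistance(ellipse_sdf(g, c(30, 48), c(20, 7)))
  infl <- redistance(ellipse_sdf(g, c(30, 48), c(30, 13)))
  ls_s <- localized_speed(In, shrunken, 8)
  ls_i <- localized_speed(In, infl, 8)
  expect_gt(mean(ls_s$values[narrowband(shrunken)] > 0), 0.9)  # expand
  expect_gt(mean(ls_i$values[narrowband(infl)] < 0), 0.9)      # contract
})

test_that("speed bounds dominate the competition speed for any state", {
  g <- tiny_grid(48)
  set.seed(11)
  I <- scalar_field(array(runif(48 * 48, 0, 10), c(48, 48)), g)
  model <- region_model("global_means")
  b <- speed_bound(model, I)
  expect_equal(b$global, (max(I$values) - min(I$values))^2)
  expect_true(all(b$pointwise$values <= b$global + 1e-12))
  expect_equal(speed_bound(model, scalar_field(4, g))$global, 0)
  bin <- scalar_field(ifelse(circle_sdf(g, c(24, 24), 9)$values > 0, 10, 2), g)
  expect_equal(speed_bound(model, bin)$global, 64)
  # |G| <= bound across a range of states, both models
  for (r in c(6, 12, 20)) {
    phi <- circle_sdf(g, c(24, 24), r)
    expect_lte(max(abs(chan_vese_speed(I, phi)$values)), b$global)
    expect_lte(max(abs(localized_speed(I, phi, 6)$values)), b$global)
  }
})

test_that("open-loop evolution monotonically decreases the energy", {
  ph <- small_phantom()
  g <- ph$I$grid
  phi0 <- circle_sdf(g, c(30, 48), 7)
  cfg <- session_config(max_steps = 120)
  res <- run_open_loop(ph$I, phi0, cfg)
  d <- res$diagnostics
  dE <- diff(d$E)
  in_block <- !d$redistanced[-1]
  expect_true(all(dE[in_block] <= 1e-6 * abs(d$E[-nrow(d)][in_block])))
})
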