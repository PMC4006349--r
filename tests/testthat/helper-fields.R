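# Shared builders and independent brute-force oracles for the test suite.

tiny_grid <- function(n = 32, spacing = 1) grid_spec(c(n, n), spacing)

# Brute-force sub-cell interface points of a 2-D field: for every axis pair
# of neighbors with a sign change, the linear-interpolation crossing point
# (in cell coordinates). Independent of the fast-sweeping code path.
interface_points <- function(values) {
  pts <- NULL
  d <- dim(values)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      v <- values[i, j]
      if (i < d[1]) {
        w <- values[i + 1, j]
        if (v == 0) pts <- rbind(pts, c(i, j))
        if (v * w < 0) pts <- rbind(pts, c(i + abs(v) / (abs(v) + abs(w)), j))
      }
      if (j < d[2]) {
        w <- values[i, j + 1]
        if (v * w < 0) pts <- rbind(pts, c(i, j + abs(v) / (abs(v) + abs(w))))
      }
    }
  }
  pts
}

# Brute-force distance from every cell to the nearest interface point.
brute_distance <- function(values) {
  pts <- interface_points(values)
  d <- dim(values)
  out <- array(NA_real_, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
    }
  }
  out
}

# Brute-force localized competition speed by direct double loop (2-D),
# mirroring the documented definition: H-weighted ball means, delta-weighted
# ball average of the Chan-Vese residual.
brute_localized_speed <- function(I, phi, r_loc) {
  d <- dim(I$values)
  H <- heaviside_eps(phi$values, phi$eps)
  del <- delta_eps(phi$values, phi$eps)
  out <- array(0, d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      if (abs(phi$values[i, j]) > phi$eps) next
      s_h <- s_hi <- s_n <- s_i <- s_d0 <- num <- 0
      for (a in seq_len(d[1])) {
        for (b in seq_len(d[2])) {
          if ((a - i)^2 + (b - j)^2 > r_loc^2) next
          s_h <- s_h + H[a, b]
          s_hi <- s_hi + H[a, b] * I$values[a, b]
          s_n <- s_n + 1
          s_i <- s_i + I$values[a, b]
        }
      }
      if (s_h < 1e-8 || (s_n - s_h) < 1e-8) next
      mu_in <- s_hi / s_h
      mu_out <- (s_i - s_hi) / (s_n - s_h)
      for (a in seq_len(d[1])) {
        for (b in seq_len(d[2])) {
          if ((a - i)^2 + (b - j)^2 > r_loc^2) next
          s_d0 <- s_d0 + del[a, b]
          num <- num + del[a, b] *
            (-(I$values[a, b] - mu_in)^2 + (I$values[a, b] - mu_out)^2)
        }
      }
      if (s_d0 > 1e-8) out[i, j] <- num / s_d0
    }
  }
  out
}

# small two-ellipse phantom for fast end-to-end tests
small_phantom <- function(noise_sd = 0.5, seed = 1) {
  make_phantom(phantom_spec(
    shape = c(96, 96), centers = list(c(30, 48), c(70, 48)),
    axes = list(c(16, 11), c(15, 10)), bridge_width = 3,
    noise_sd = noise_sd, seed = seed))
}
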