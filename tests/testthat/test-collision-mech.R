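make_movie <- function(fun, xs = seq(44, 4356, by = 88),
                       ys = seq(44, 2956, by = 88),
                       ts = seq(0, 10, by = 1), kind = "v_x") {
  vals <- array(NA_real_, dim = c(length(ys), length(xs), length(ts)))
  xx <- rep(xs, each = length(ys))
  yy <- rep(ys, times = length(xs))
  for (s in seq_along(ts)) {
    v <- fun(xx, yy, ts[s])
    if (length(v) == 1) v <- rep(v, length(xx))
    vals[, , s] <- matrix(v, length(ys), length(xs))
  }
  field_movie(xs, ys, ts, vals, kind = kind)
}

test_that("kymographs band-average correctly and respect missing data", {
  # uniform field: all entries equal the constant
  k1 <- build_kymograph(make_movie(function(x, y, t) 7), band_margin = 1000)
  expect_true(all(k1$values == 7))
  expect_equal(k1$band, c(1044, 1948))

  # linear profile is reproduced per timepoint
  k2 <- build_kymograph(make_movie(function(x, y, t) 0.01 * x),
                        time_smooth = FALSE)
  expect_equal(k2$values[, 3], 0.01 * k2$x, tolerance = 1e-12)

  # margin too large is an error
  expect_error(build_kymograph(make_movie(function(x, y, t) 1),
                               band_margin = 1600), "margin")

  # y-averaging reduces noise like 1/sqrt(n_rows)
  set.seed(5)
  noisy <- make_movie(function(x, y, t) rnorm(length(x), 0, 10))
  k3 <- build_kymograph(noisy, band_margin = 1000, time_smooth = FALSE)
  n_rows <- sum(noisy$y >= 1044 & noisy$y <= 1956)
  expect_lt(max(abs(k3$values)), 5 * 10 / sqrt(n_rows))

  # all-NA columns stay missing, never zero-filled
  part <- make_movie(function(x, y, t) ifelse(x < 2000, 1, NA))
  k4 <- build_kymograph(part)
  expect_true(all(is.na(k4$values[k4$x > 2100, ])))
  expect_true(all(k4$values[k4$x < 1900, ] == 1))
})

test_that("kymograph averaging aligns, averages and sets the median extent", {
  k <- build_kymograph(make_movie(function(x, y, t) 0.01 * x),
                       time_smooth = FALSE)
  # identical copies average to themselves
  ka <- average_kymographs(list(k, k, k))
  expect_equal(ka$values, k$values)

  # c and -c cancel
  kp <- build_kymograph(make_movie(function(x, y, t) 2), time_smooth = FALSE)
  km <- build_kymograph(make_movie(function(x, y, t) -2), time_smooth = FALSE)
  expect_true(all(average_kymographs(list(kp, km))$values == 0))

  # five noisy replicates: residual RMS ~ sigma / sqrt(5)
  set.seed(9)
  reps <- lapply(1:5, function(i)
    build_kymograph(make_movie(function(x, y, t) rnorm(length(x), 0, 1)),
                    band_margin = 1400, time_smooth = FALSE))
  avg <- average_kymographs(reps)
  sd_bin <- 1 / sqrt(sum(reps[[1]]$band[1] <= seq(44, 2956, 88) &
                           seq(44, 2956, 88) <= reps[[1]]$band[2]))
  rms <- sqrt(mean(avg$values^2))
  expect_lt(abs(rms / (sd_bin / sqrt(5)) - 1), 0.25)

  expect_error(average_kymographs(list(k, structure(
    modifyList(k, list(bin = 44)), class = "kymograph"))), "bin widths")
})

test_that("center of expansion finds the stall midline", {
  # divergent flow about x_c: trace sits at x_c within half a bin
  xc <- 2222
  k <- build_kymograph(make_movie(function(x, y, t) 0.05 * (x - xc)),
                       time_smooth = FALSE)
  ce <- center_of_expansion(k)
  expect_true(all(abs(ce$x - xc) <= 44))

  # nothing below threshold: missing
  kfast <- build_kymograph(make_movie(function(x, y, t) 10 + 0.001 * x),
                           time_smooth = FALSE)
  expect_true(all(is.na(center_of_expansion(kfast)$x)))

  # programmed linear drift of the center is recovered within one bin
  drift <- function(t) 1800 + 60 * t
  kd <- build_kymograph(make_movie(function(x, y, t) 0.05 * (x - drift(t))),
                        time_smooth = FALSE)
  ced <- center_of_expansion(kd)
  expect_true(all(abs(ced$x - drift(kd$t)) <= 88))
})

test_that("boundary velocity is a windowed least-squares slope", {
  tr <- data.frame(t = seq(0, 40, by = 0.5), x = 1000)
  expect_equal(boundary_velocity(tr), 0)
  tr2 <- data.frame(t = seq(0, 40, by = 0.5))
  tr2$x <- 800 + 10 * tr2$t
  expect_equal(boundary_velocity(tr2), 10)
  # noisy drift recovered
  set.seed(31)
  tr3 <- data.frame(t = seq(0, 40, by = 1 / 3))
  tr3$x <- 1000 + 8 * tr3$t + rnorm(nrow(tr3), 0, 5)
  expect_lt(abs(boundary_velocity(tr3) - 8), 1)
  expect_error(boundary_velocity(tr3[tr3$t < 20.4, ]), "fewer than 3")
})

test_that("window counting converts nuclei to densities", {
  g <- tiss_grid(88, world = c(2000, 2000))
  # homogeneous Poisson pattern at 2000 cells/mm^2 over 4 mm^2
  set.seed(12)
  n <- rpois(1, 2000 * 4)
  nuc <- data.frame(x_um = runif(n, 0, 2000), y_um = runif(n, 0, 2000))
  d <- density_from_nuclei(nuc, g)
  inner <- d$values[2:21, 2:21, 1]     # whole windows only
  expect_lt(abs(mean(inner) - 2000), 50)

  # no points -> all-zero field
  d0 <- density_from_nuclei(nuc[0, ], g)
  expect_true(all(d0$values == 0))

  # one point in one 88 um window
  d1 <- density_from_nuclei(data.frame(x_um = 100, y_um = 100), g)
  expect_equal(max(d1$values), 1 / 0.088^2)
  expect_equal(sum(d1$values > 0), 1)
})

test_that("density gradients at the boundary follow the two-window rule", {
  xs <- seq(44, 4356, by = 88)
  prof_movie <- function(fun) make_movie(fun, kind = "density")

  expect_true(all(density_gradient_at_boundary(
    prof_movie(function(x, y, t) 2000), 2200)$drho_dx == 0))

  # linear profile: exact when the side regions align with window edges
  # (windows are 88 um wide with edges on multiples of 88)
  lin <- prof_movie(function(x, y, t) 1000 + 0.8 * x)
  g <- density_gradient_at_boundary(lin, 2200, width = 264)
  expect_equal(unique(g$drho_dx), 0.8, tolerance = 1e-12)
  # within the window discretization at the default region width
  g300 <- density_gradient_at_boundary(lin, 2217)
  expect_lt(abs(unique(g300$drho_dx) / 0.8 - 1), 0.01)

  # step profile 2600 | 1800 at the boundary: (1800 - 2600) / 300 = -2.67
  step <- prof_movie(function(x, y, t) ifelse(x < 2200, 2600, 1800))
  gs <- density_gradient_at_boundary(step, 2200)
  expect_equal(unique(gs$drho_dx), -800 / 300)

  expect_error(density_gradient_at_boundary(step, 100), "outside the data")
})

test_that("pressure-velocity relation has the right sign, units and scaling", {
  expect_equal(pressure_velocity(0, 0.5, 100), 0)
  # P' = 0.5 Pa mm^2, xi = 100 Pa s/um^2, gradient -8/3 cells/(mm^2 um)
  expect_equal(pressure_velocity(-800 / 300, 0.5, 100), 48, tolerance = 1e-9)
  # linear in P'
  expect_equal(pressure_velocity(-1, 1, 100),
               2 * pressure_velocity(-1, 0.5, 100))
  # sign law: velocity always opposes the gradient
  set.seed(3)
  gr <- runif(50, -3, 3)
  v <- pressure_velocity(gr, 0.5, 100)
  expect_true(all(sign(v[gr != 0]) == -sign(gr[gr != 0])))
  # dimension audit: the um/h result equals the um/s force balance times 3600
  expect_equal(pressure_velocity(-2, 0.7, 50), -(0.7 / 50) * (-2) * 3600)
  expect_error(pressure_velocity(1, 0.5, xi = 0), "positive")
})

test_that("fit_pressure_slope inverts the model and flags degenerate input", {
  g <- seq(-3, -0.2, length.out = 12)
  pairs <- data.frame(drho_dx = g, v = pressure_velocity(g, 0.5, 100))
  fit <- fit_pressure_slope(pairs, xi = 100)
  expect_equal(fit$P_prime, 0.5, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[["intercept"]]), 0, tolerance = 1e-9)
  expect_equal(fit$r, -1)

  # assay averaging: the line goes through group means
  assay <- rep(1:3, each = 4)
  fit2 <- fit_pressure_slope(pairs, xi = 100, assay = assay, rho = 3400)
  expect_equal(fit2$P_prime, 0.5, tolerance = 1e-12)
  expect_equal(fit2$K, 1700, tolerance = 1e-9)
  expect_equal(nrow(fit2$means), 3)

  # model-object methods behave
  expect_equal(unname(predict(fit, data.frame(drho_dx = -1))),
               pressure_velocity(-1, 0.5, 100), tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  expect_output(print(fit), "P'")
  expect_output(print(suppressWarnings(summary(fit))), "Linear fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(12L, 2L))

  expect_error(fit_pressure_slope(
    data.frame(drho_dx = rep(-1, 5), v = rnorm(5)), xi = 100), "degenerate")

  # through-origin option
  fit3 <- fit_pressure_slope(pairs, xi = 100, through_origin = TRUE)
  expect_equal(fit3$P_prime, 0.5, tolerance = 1e-12)
})

test_that("equation of state and moduli conversions are exact", {
  expect_equal(bulk_modulus(0.5, 3.4e3), 1700)
  expect_equal(bulk_modulus(0, 3.4e3), 0)
  expect_equal(bulk_modulus(0.5, 6.8e3), 2 * bulk_modulus(0.5, 3.4e3))
  expect_error(bulk_modulus(0.5, -1), "positive")

  expect_equal(eos_pressure(1500, 2000, 1500), 0)
  expect_equal(eos_pressure(exp(1) * 1500, 2000, 1500), 2000)
  # numerical dP/drho matches K / rho
  rho <- 3400; h <- 1e-3
  dnum <- (eos_pressure(rho + h, 1700, 1500) -
             eos_pressure(rho - h, 1700, 1500)) / (2 * h)
  expect_lt(abs(dnum / (1700 / rho) - 1), 1e-6)
  expect_error(eos_pressure(-1, 1700, 1500), "positive")

  expect_equal(stiffness_from_tension(2.4, 5), 0.48)
  expect_equal(stiffness_from_tension(0, 5), 0)
  expect_equal(stiffness_from_tension(2.4, 10),
               stiffness_from_tension(2.4, 5) / 2)
  expect_error(stiffness_from_tension(2.4, 0), "positive")
})

test_that("field tables and kymographs round-trip through text files", {
  m <- make_movie(function(x, y, t) 0.01 * x + t, ts = 0:3)
  p <- tempfile(fileext = ".csv")
  write_field_table(m, p)
  back <- read_field_table(p)
  expect_equal(back$values, m$values)
  expect_equal(back$x, m$x)
  expect_equal(back$t, m$t)

  k <- build_kymograph(m, time_smooth = FALSE)
  pk <- tempfile(fileext = ".csv")
  write_kymograph(k, pk)
  kb <- read_kymograph(pk)
  expect_equal(kb$values, k$values)
  expect_equal(kb$t, k$t)
})
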