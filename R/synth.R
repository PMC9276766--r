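#' Generate a synthetic collision assay with known ground truth
#'
#' Emulates a two-rectangle collision experiment end to end: label movie,
#' PIV-style v_x field, window-counted density field, nuclei point pattern,
#' and the ground truth that produced them. The generator is an independent
#' forward model (it shares only the pressure-velocity formula with the
#' analysis code), so every analysis operation can be validated against known
#' truth.
#'
#' Model, all 1D along the collision axis with independent per-row noise:
#' * Before collision each tissue expands about its centroid with a linear
#'   (divergent) velocity profile reaching the normal speed `v_n` at its
#'   edges, so the tissue dilutes uniformly as it spreads; cell density also
#'   grows logistically toward `rho_max`.
#' * The facing edges meet at the gap midline (for equal speeds); from the
#'   fusion time on, the boundary moves by pressure-driven flow:
#'   `v_b = -(P_prime / xi) * drho/dx * 3600`, where the gradient is the
#'   operational two-sided 300-um-window difference on the generator's own
#'   density profile.
#' * The post-fusion velocity field is piecewise linear and divergent about a
#'   center of expansion that relaxes exponentially (timescale
#'   `center_relax`) from the centroid of the denser/wider tissue at fusion
#'   toward the fused tissue's centroid, clipped to the normal speed at the
#'   outer edges; the field passes through `v_b` at the boundary, so the
#'   boundary is a material point of the flow.
#' * Density evolves by the 1D continuity equation under this velocity field
#'   (conservative upwind finite volumes), plus logistic growth and an
#'   optional lateral diffusion `density_diffusion` that relaxes the density
#'   step after fusion (the relaxation rate of real boundary gradients is not
#'   firmly established, hence a parameter).
#' * Gaussian noise is added per window: additive `noise_v` (um/h) on
#'   velocity, multiplicative `noise_density_frac` on density. Nuclei are an
#'   inhomogeneous Poisson pattern matching the noiseless density field.
#'
#' With `growth_rate = 0`, `density_diffusion = 0` and zero noise the output
#' fields satisfy the 1D continuity equation up to discretization error.
#'
#' @param widths initial tissue widths along x, um.
#' @param gap initial free gap between the facing edges, um.
#' @param height tissue extent along y, um.
#' @param densities initial cell densities, cells/mm^2.
#' @param v_n normal edge speeds, um/h.
#' @param P_prime,xi mechanics ground truth: pressure-density slope (Pa mm^2)
#'   and friction coefficient (Pa s/um^2).
#' @param growth_rate logistic growth rate, 1/h.
#' @param rho_max logistic carrying capacity, cells/mm^2.
#' @param density_diffusion lateral density diffusion, um^2/h.
#' @param center_relax relaxation timescale of the center of expansion, h.
#' @param noise_v additive velocity noise SD per window, um/h.
#' @param noise_density_frac multiplicative density noise SD per window.
#' @param t_end,dt movie length and cadence, h.
#' @param window PIV window size, um.
#' @param label_spacing pixel size of the label movie, um.
#' @param fine_dx internal fine-grid resolution, um.
#' @param nuclei_every sample nuclei every this many hours (`NA` to skip).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param sc optional two-rectangle (axis-aligned) [scene]; overrides
#'   `widths`, `gap`, `height`, `densities`, `v_n`. Any other scene is an
#'   error (the generator's scope is binary rectangle collisions).
#' @return A list of class `synth_collision`: `movie` ([label_movie]), `vx`
#'   and `density` ([field_movie]s), `nuclei` (data frame `x_um, y_um, t_h`),
#'   and `truth` (list: `boundary` and `center` data frames (`t`, `x`),
#'   `gradient` and `v_boundary` data frames, `P_prime`, `xi`, `fusion_time`,
#'   `fusion_x`, `profiles` (fine-grid density matrix, cells x timepoints),
#'   `fine_x`, `params`, `seed`).
#' @export
synth_collision <- function(widths = c(1000, 1000), gap = 500, height = 3000,
                            densities = c(2600, 1800), v_n = c(29.5, 29.5),
                            P_prime = 0.5, xi = 100,
                            growth_rate = 0.035, rho_max = 6000,
                            density_diffusion = 2000, center_relax = 12,
                            noise_v = 2, noise_density_frac = 0.08,
                            t_end = 40, dt = 1 / 3, window = 88,
                            label_spacing = 20, fine_dx = 10,
                            nuclei_every = 4, seed = NULL, sc = NULL) {
  if (!is.null(sc)) {
    g <- rectangles_from_scene(sc)
    widths <- g$widths; gap <- g$gap; height <- g$height
    densities <- g$densities %||% densities
    v_n <- g$v_n
  }
  stopifnot(length(widths) == 2, all(widths > 0), gap > 0, height > 0,
            length(densities) == 2, all(densities > 0),
            length(v_n) == 2, all(v_n >= 0), xi > 0,
            growth_rate >= 0, rho_max > 0, density_diffusion >= 0,
            center_relax > 0, noise_v >= 0, noise_density_frac >= 0)
  if (!is.null(seed)) set.seed(seed)
  v1 <- v_n[1]; v2 <- v_n[2]
  grad_width <- 300

  # world sized so free edges never leave it
  padL <- v1 * t_end + 2 * window
  padR <- v2 * t_end + 2 * window
  e1L <- padL; e1R <- e1L + widths[1]
  e2L <- e1R + gap; e2R <- e2L + widths[2]
  world_w <- e2R + padR
  nxf <- as.integer(ceiling(world_w / fine_dx))
  xf <- (seq_len(nxf) - 0.5) * fine_dx          # cell centers
  faces <- (0:nxf) * fine_dx

  # fractional cell coverage keeps the initial profile exactly symmetric
  # when the configuration is symmetric
  coverage <- function(a1, a2)
    pmax(0, pmin(a2, xf + fine_dx / 2) - pmax(a1, xf - fine_dx / 2)) / fine_dx
  rho <- densities[1] * coverage(e1L, e1R) + densities[2] * coverage(e2L, e2R)

  times <- seq(0, t_end, by = dt)
  nt <- length(times)
  # explicit-scheme stability (advection Courant ~0.5, diffusion ~0.4)
  dt_sub <- min(if (max(v_n) > 0) 0.5 * fine_dx / max(v_n) else Inf,
                if (density_diffusion > 0)
                  0.4 * fine_dx^2 / density_diffusion else Inf,
                dt)
  n_sub <- max(1L, ceiling(dt / dt_sub - 1e-9))
  dt_s <- dt / n_sub

  # output window grids
  nxw <- as.integer(floor(world_w / window))
  nyw <- as.integer(floor(height / window))
  wx <- (seq_len(nxw) - 0.5) * window
  wy <- (seq_len(nyw) - 0.5) * window
  cell_win <- factor(pmin(ceiling(xf / window), nxw), levels = seq_len(nxw))
  # label grid
  nxl <- as.integer(floor(world_w / label_spacing))
  nyl <- as.integer(floor(height / label_spacing))
  lgrid <- tiss_grid(label_spacing, nx = nxl, ny = nyl,
                     origin = c(label_spacing / 2, label_spacing / 2))
  xl <- grid_x(lgrid)

  fused <- FALSE; b <- NA_real_; t_fus <- NA_real_; fus_x <- NA_real_
  xe_amp <- 0; x_e <- NA_real_
  mass1 <- densities[1] * widths[1]; mass2 <- densities[2] * widths[2]

  # operational two-sided window gradient on the fine-grid profile, with
  # fractional cell coverage at the interval ends so it is exactly symmetric
  win_gradient <- function(rho, b) {
    wmean <- function(a1, a2) {
      wt <- pmax(0, pmin(a2, xf + fine_dx / 2) - pmax(a1, xf - fine_dx / 2))
      sum(wt * rho) / sum(wt)
    }
    (wmean(b, b + grad_width) - wmean(b - grad_width, b)) / grad_width
  }
  vel_profile <- function(x, t) {
    if (!fused) {
      m <- (e1R + e2L) / 2
      out <- numeric(length(x))
      i1 <- x <= m
      out[i1] <- stats::approx(c(e1L, (e1L + e1R) / 2, e1R),
                               c(-v1, 0, v1), x[i1], rule = 2)$y
      out[!i1] <- stats::approx(c(e2L, (e2L + e2R) / 2, e2R),
                                c(-v2, 0, v2), x[!i1], rule = 2)$y
      out
    } else {
      kx <- c(e1L, x_e, b, e2R)
      kv <- c(-v1, 0, v_b_cur, v2)
      ord <- order(kx)
      kx <- kx[ord]; kv <- kv[ord]
      keep <- c(TRUE, diff(kx) > fine_dx / 2)
      stats::approx(kx[keep], kv[keep], x, rule = 2)$y
    }
  }

  vx_vals <- array(NA_real_, dim = c(nyw, nxw, nt))
  rho_vals <- array(NA_real_, dim = c(nyw, nxw, nt))
  rho_clean <- matrix(NA_real_, nxw, nt)
  fields <- vector("list", nt)
  profiles <- matrix(0, nxf, nt)
  truth_b <- truth_xe <- truth_G <- truth_vb <- rep(NA_real_, nt)
  v_b_cur <- 0

  record_frame <- function(s) {
    # analytic tissue intervals
    if (!fused) {
      int1 <- c(e1L, e1R); int2 <- c(e2L, e2R)
    } else {
      int1 <- c(e1L, b); int2 <- c(b, e2R)
    }
    inside <- (xf >= int1[1] & xf <= int1[2]) | (xf >= int2[1] & xf <= int2[2])
    vfine <- vel_profile(xf, times[s])
    v_win <- rep(NA_real_, nxw); r_win <- rep(NA_real_, nxw)
    frac <- tapply(inside, cell_win, mean)
    vm <- tapply(ifelse(inside, vfine, NA), cell_win, mean, na.rm = TRUE)
    rm_ <- tapply(rho, cell_win, mean)        # count-style: zeros included
    ok <- !is.na(frac) & frac >= 0.5
    v_win[ok] <- vm[ok]
    r_win[ok] <- rm_[ok]
    rho_clean[, s] <<- r_win
    vx_vals[, , s] <<- matrix(rep(v_win, each = nyw), nyw, nxw) +
      if (noise_v > 0) stats::rnorm(nyw * nxw, sd = noise_v) else 0
    rho_vals[, , s] <<- pmax(
      matrix(rep(r_win, each = nyw), nyw, nxw) *
        (1 + if (noise_density_frac > 0)
          stats::rnorm(nyw * nxw, sd = noise_density_frac) else 0), 0)
    lab <- integer(nxl)
    lab[xl >= int1[1] & xl <= int1[2]] <- 1L
    lab[xl >= int2[1] & xl <= int2[2] & lab == 0L] <- 2L
    fields[[s]] <<- label_field(matrix(rep(lab, each = nyl), nyl, nxl),
                                lgrid, time = times[s])
    profiles[, s] <<- rho
    truth_b[s] <<- if (fused) b else NA_real_
    truth_xe[s] <<- if (fused) x_e else NA_real_
    truth_G[s] <<- if (fused) win_gradient(rho, b) else NA_real_
    truth_vb[s] <<- if (fused) v_b_cur else NA_real_
  }

  record_frame(1)

  for (s in 2:nt) {
    for (k in seq_len(n_sub)) {
      t_now <- times[s - 1] + (k - 1) * dt_s
      if (fused) {
        G <- win_gradient(rho, b)
        v_b_cur <- pressure_velocity(G, P_prime, xi)
        c_f <- (e1L + e2R) / 2
        x_e <- c_f + xe_amp * exp(-(t_now - t_fus) / center_relax)
      }
      vface <- vel_profile(faces, t_now)
      # conservative upwind advection
      rho_up <- ifelse(vface > 0, c(0, rho), c(rho, 0))
      Fadv <- vface * rho_up
      rho <- rho - dt_s / fine_dx * (Fadv[-1] - Fadv[-length(Fadv)])
      # analytic tissue mask for growth/diffusion gating
      if (!fused) {
        inside <- (xf >= e1L & xf <= e1R) | (xf >= e2L & xf <= e2R)
      } else inside <- xf >= e1L & xf <= e2R
      if (growth_rate > 0)
        rho[inside] <- rho[inside] + dt_s * growth_rate * rho[inside] *
          (1 - rho[inside] / rho_max)
      if (density_diffusion > 0) {
        dflux <- -density_diffusion * diff(rho) / fine_dx
        dflux[!(inside[-nxf] & inside[-1])] <- 0
        rho <- rho - dt_s / fine_dx * (c(dflux, 0) - c(0, dflux))
      }
      rho <- pmax(rho, 0)
      # move edges / boundary
      e1L <- e1L - v1 * dt_s
      e2R <- e2R + v2 * dt_s
      if (!fused) {
        e1R <- e1R + v1 * dt_s
        e2L <- e2L - v2 * dt_s
        if (e1R >= e2L) {
          fused <- TRUE
          b <- (e1R + e2L) / 2
          t_fus <- t_now + dt_s
          fus_x <- b
          c_f <- (e1L + e2R) / 2
          c_d <- if (mass1 > mass2) (e1L + b) / 2
                 else if (mass2 > mass1) (b + e2R) / 2 else c_f
          xe_amp <- c_d - c_f
          x_e <- c_d
          v_b_cur <- pressure_velocity(win_gradient(rho, b), P_prime, xi)
        }
      } else {
        b <- b + v_b_cur * dt_s
      }
    }
    record_frame(s)
  }

  vx <- field_movie(wx, wy, times, vx_vals, kind = "v_x")
  dens <- field_movie(wx, wy, times, rho_vals, kind = "density")

  nuclei_parts <- list()
  if (is.finite(nuclei_every) && !is.na(nuclei_every)) {
    samp <- which(abs(times / nuclei_every - round(times / nuclei_every)) <
                    1e-9)
    area_mm2 <- (window / 1000)^2
    for (s in samp) {
      lam <- rho_clean[, s] * area_mm2
      lam[is.na(lam)] <- 0
      for (j in which(lam > 0)) {
        n <- stats::rpois(nyw, lam[j])
        tot <- sum(n)
        if (!tot) next
        nuclei_parts[[length(nuclei_parts) + 1]] <- data.frame(
          x_um = wx[j] + stats::runif(tot, -window / 2, window / 2),
          y_um = rep(wy, n) + stats::runif(tot, -window / 2, window / 2),
          t_h = times[s])
      }
    }
  }
  nuclei <- if (length(nuclei_parts)) do.call(rbind, nuclei_parts) else
    data.frame(x_um = numeric(0), y_um = numeric(0), t_h = numeric(0))

  truth <- list(
    boundary = data.frame(t = times, x = truth_b),
    center = data.frame(t = times, x = truth_xe),
    gradient = data.frame(t = times, drho_dx = truth_G),
    v_boundary = data.frame(t = times, v = truth_vb),
    P_prime = P_prime, xi = xi,
    fusion_time = t_fus, fusion_x = fus_x,
    profiles = profiles, fine_x = xf,
    params = list(widths = widths, gap = gap, height = height,
                  densities = densities, v_n = v_n,
                  growth_rate = growth_rate, rho_max = rho_max,
                  density_diffusion = density_diffusion,
                  center_relax = center_relax, noise_v = noise_v,
                  noise_density_frac = noise_density_frac,
                  t_end = t_end, dt = dt, window = window,
                  label_spacing = label_spacing, fine_dx = fine_dx),
    seed = seed)

  structure(list(movie = label_movie(fields, speeds = c(`1` = v1, `2` = v2)),
                 vx = vx, density = dens, nuclei = nuclei, truth = truth),
            class = "synth_collision")
}

#' @export
print.synth_collision <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "<synth_collision> %g+%g um tissues, gap %g um, rho0 = %g/%g cells/mm^2\n",
    p$widths[1], p$widths[2], p$gap, p$densities[1], p$densities[2]))
  cat(sprintf("  fusion at t = %.2f h, x = %.0f um; P' = %g Pa mm^2, xi = %g\n",
              x$truth$fusion_time, x$truth$fusion_x, x$truth$P_prime,
              x$truth$xi))
  invisible(x)
}

rectangles_from_scene <- function(sc) {
  if (!inherits(sc, "scene")) stop("`sc` must be a scene")
  if (length(sc$tissues) != 2)
    stop("the collision generator needs a two-tissue scene")
  for (t in sc$tissues)
    if (t$shape$kind != "rectangle" || (t$shape$angle %% 180) != 0)
      stop("the collision generator supports axis-aligned rectangle seeds only")
  s1 <- sc$tissues[[1]]$shape; s2 <- sc$tissues[[2]]$shape
  if (s1$center[1] > s2$center[1]) { tmp <- s1; s1 <- s2; s2 <- tmp }
  gap <- (s2$center[1] - s2$width / 2) - (s1$center[1] + s1$width / 2)
  if (gap <= 0) stop("rectangles must be separated along x")
  v <- speeds(sc)
  dens <- lapply(sc$tissues, function(t) t$density)
  list(widths = c(s1$width, s2$width), gap = gap,
       height = min(s1$height, s2$height),
       densities = if (!any(vapply(dens, is.null, logical(1))))
         unlist(dens) else NULL,
       v_n = as.numeric(v))
}

#' Synthetic boundary-velocity vs density-gradient pairs
#'
#' Draws density gradients uniformly over `gradient_range` and maps them to
#' boundary velocities through the pressure-driven flow relation
#' ([pressure_velocity]), with multiplicative Gaussian noise. Used to test
#' recovery of the pressure-density slope by [fit_pressure_slope].
#'
#' @param P_prime pressure-density slope, Pa mm^2.
#' @param xi friction coefficient, Pa s/um^2.
#' @param n number of pairs (>= 2).
#' @param noise_frac multiplicative noise SD (>= 0).
#' @param seed integer seed for reproducibility.
#' @param gradient_range range of gradients, cells/(mm^2 um).
#' @return Data frame with columns `drho_dx` and `v` (um/h).
#' @export
synth_velocity_density_pairs <- function(P_prime, xi, n, noise_frac = 0.1,
                                         seed = NULL,
                                         gradient_range = c(-3, 0)) {
  if (n < 2) stop("need n >= 2 pairs")
  if (noise_frac < 0) stop("`noise_frac` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  g <- stats::runif(n, gradient_range[1], gradient_range[2])
  v <- pressure_velocity(g, P_prime, xi) *
    (1 + stats::rnorm(n, sd = noise_frac))
  data.frame(drho_dx = g, v = v)
}

#' Sample nuclei centroids from a density field
#'
#' Inhomogeneous Poisson point pattern: each window contributes
#' `Poisson(density * window area)` points placed uniformly within the
#' window. `NA` or zero-density windows contribute none.
#'
#' @param density a density [field_movie], cells/mm^2.
#' @param seed integer seed.
#' @return Data frame with columns `x_um`, `y_um`, `t_h`.
#' @export
synth_nuclei <- function(density, seed = NULL) {
  if (!inherits(density, "field_movie")) stop("`density` must be a field_movie")
  if (!is.null(seed)) set.seed(seed)
  pitch <- window_pitch(density)
  area_mm2 <- (pitch / 1000)^2
  out <- vector("list", length(density$t))
  for (s in seq_along(density$t)) {
    lam <- density$values[, , s] * area_mm2
    lam[is.na(lam) | lam < 0] <- 0
    n <- stats::rpois(length(lam), lam)
    tot <- sum(n)
    if (!tot) next
    w <- which(n > 0)
    i <- (w - 1L) %% length(density$y) + 1L
    j <- (w - 1L) %/% length(density$y) + 1L
    out[[s]] <- data.frame(
      x_um = rep(density$x[j], n[w]) + stats::runif(tot, -pitch/2, pitch/2),
      y_um = rep(density$y[i], n[w]) + stats::runif(tot, -pitch/2, pitch/2),
      t_h = density$t[s])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(x_um = numeric(0), y_um = numeric(0), t_h = numeric(0)))
  do.call(rbind, out)
}
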