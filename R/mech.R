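#' Boundary velocity from a boundary trace
#'
#' Least-squares slope of the boundary position against time over an
#' analysis window, the operational definition of post-collision boundary
#' velocity. The default window of 20-36 h targets the interval after
#' collision and before the boundary stalls; adjust it to the assay.
#'
#' @param trace a `boundary_trace` (or any data frame with columns `t`, `x`).
#' @param window `c(t1, t2)` in hours.
#' @return Velocity in um/h.
#' @export
boundary_velocity <- function(trace, window = c(20, 36)) {
  sel <- trace$t >= window[1] & trace$t <= window[2] & !is.na(trace$x)
  if (sum(sel) < 3)
    stop("fewer than 3 defined trace points in the window [",
         window[1], ", ", window[2], "] h")
  unname(stats::coef(stats::lm(x ~ t, data = trace[sel, ]))[2])
}

#' Cell density gradient at the boundary
#'
#' The operational density gradient: mean density within a `width`-wide
#' region immediately right of the boundary minus the mean within the region
#' immediately left, divided by `width` (default 300 um). Window values are
#' weighted by their fractional overlap with each side region; for a linear
#' density profile the estimate is exact whenever the regions align with
#' window boundaries, and accurate to the window discretization (well under
#' 1%) otherwise.
#'
#' @param density a density [field_movie] (cells/mm^2) or a density
#'   `kymograph`.
#' @param boundary_x boundary position(s), um: a scalar applied to all
#'   timepoints or one value per timepoint (`NA` skipped).
#' @param width side-region width, micrometres.
#' @param times optional subset of timepoints (h) to evaluate.
#' @return Data frame with columns `t` (h) and `drho_dx`
#'   (cells/(mm^2 um)).
#' @export
density_gradient_at_boundary <- function(density, boundary_x, width = 300,
                                         times = NULL) {
  if (inherits(density, "kymograph")) {
    x <- density$x; tt <- density$t
    prof <- density$values                      # nx x nt
  } else if (inherits(density, "field_movie")) {
    x <- density$x; tt <- density$t
    prof <- apply(density$values, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    prof <- matrix(prof, length(x), length(tt))
  } else stop("`density` must be a field_movie or kymograph")
  if (is.null(times)) times <- tt
  keep <- which(tt %in% times)
  bx <- rep_len(boundary_x, length(tt))
  pitch <- if (length(x) > 1) diff(x[1:2]) else width
  g <- vapply(keep, function(s) {
    b <- bx[s]
    if (is.na(b)) return(NA_real_)
    if (b - width < x[1] - pitch / 2 - 1e-9 ||
        b + width > x[length(x)] + pitch / 2 + 1e-9)
      stop("side region at t = ", tt[s], " h lies outside the data")
    w_all_l <- pmax(0, pmin(b, x + pitch / 2) - pmax(b - width, x - pitch / 2))
    w_all_r <- pmax(0, pmin(b + width, x + pitch / 2) - pmax(b, x - pitch / 2))
    vals <- prof[, s]
    wl <- w_all_l; wl[!is.finite(vals)] <- 0
    wr <- w_all_r; wr[!is.finite(vals)] <- 0
    if (sum(wl) <= 0 || sum(wr) <= 0)
      stop("side region at t = ", tt[s], " h lies outside the data")
    ml <- sum(wl * ifelse(wl > 0, vals, 0)) / sum(wl)
    mr <- sum(wr * ifelse(wr > 0, vals, 0)) / sum(wr)
    (mr - ml) / width
  }, numeric(1))
  data.frame(t = tt[keep], drho_dx = g)
}

#' Boundary velocity predicted by pressure-driven flow
#'
#' In the active-medium force balance, cell-substrate friction balances the
#' pressure gradient, `-grad P = xi v`; with pressure a function of cell
#' density this gives `v = -(P'(rho) / xi) grad rho`. The boundary therefore
#' moves from high to low density, at a speed proportional to the local
#' density gradient.
#'
#' Units: `P_prime` in Pa mm^2 (pressure increase per unit density increase),
#' `xi` in Pa s/um^2, gradient in cells/(mm^2 um); the product is um/s and is
#' converted to um/h.
#'
#' @param drho_dx density gradient at the boundary, cells/(mm^2 um).
#' @param P_prime slope of the pressure-density relation, Pa mm^2.
#' @param xi cell-substrate friction coefficient, Pa s/um^2 (default 100, a
#'   literature-scale value).
#' @return Boundary velocity, um/h (opposite sign to the gradient).
#' @export
pressure_velocity <- function(drho_dx, P_prime, xi = 100) {
  if (!is.numeric(xi) || xi <= 0) stop("`xi` must be positive")
  -(P_prime / xi) * drho_dx * 3600
}

#' Fit the pressure-density slope from boundary motion
#'
#' Fits the pressure-driven flow model to measured (density gradient,
#' boundary velocity) pairs: a least-squares line through the assay-average
#' points, as done when each assay type contributes one summary point; the
#' correlation coefficient `r` is reported over the individual pairs. From
#' the fitted slope `s` (um/h per cells/(mm^2 um)) the pressure-density slope
#' is `P' = -s * xi / 3600` (Pa mm^2), and with a mean density `rho` the bulk
#' modulus `K = P' * rho` follows.
#'
#' @param pairs data frame with columns `drho_dx` (cells/(mm^2 um)) and `v`
#'   (um/h), one row per measurement.
#' @param xi friction coefficient, Pa s/um^2.
#' @param assay optional factor grouping rows into assays; the line is fitted
#'   through assay means. Default: every row is its own assay.
#' @param rho optional mean cell density (cells/mm^2) for a bulk-modulus
#'   estimate.
#' @param through_origin constrain the fitted line through the origin
#'   (whether the canonical fit is constrained is ambiguous; unconstrained is
#'   the default).
#' @return An object of class `mech_fit` with components `coefficients`
#'   (intercept, slope), `P_prime` (Pa mm^2), `xi`, `r` (correlation over
#'   individual pairs), `rho`, `K` (Pa, if `rho` given), `pairs`, `means`
#'   and the underlying `lm` fit. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `simulate`, `plot`.
#' @examples
#' pairs <- synth_velocity_density_pairs(P_prime = 0.5, xi = 100, n = 25,
#'                                       noise_frac = 0.1, seed = 7)
#' fit <- fit_pressure_slope(pairs, xi = 100, rho = 3400)
#' coef(fit)
#' fit$P_prime
#' @export
fit_pressure_slope <- function(pairs, xi = 100, assay = NULL, rho = NULL,
                               through_origin = FALSE) {
  if (!all(c("drho_dx", "v") %in% names(pairs)))
    stop("`pairs` needs columns drho_dx and v")
  pairs <- pairs[is.finite(pairs$drho_dx) & is.finite(pairs$v), , drop = FALSE]
  if (nrow(pairs) < 2) stop("need at least 2 pairs")
  if (xi <= 0) stop("`xi` must be positive")
  if (is.null(assay)) assay <- seq_len(nrow(pairs))
  assay <- factor(assay)
  means <- data.frame(
    drho_dx = tapply(pairs$drho_dx, assay, mean),
    v = tapply(pairs$v, assay, mean))
  if (stats::var(means$drho_dx) < .Machine$double.eps * 100)
    stop("degenerate fit: all assay-average gradients are identical")
  fit <- if (through_origin) stats::lm(v ~ drho_dx + 0, data = means)
         else stats::lm(v ~ drho_dx, data = means)
  cf <- stats::coef(fit)
  slope <- unname(cf[["drho_dx"]])
  intercept <- if (through_origin) 0 else unname(cf[[1]])
  P_prime <- -slope * xi / 3600
  K <- if (!is.null(rho)) P_prime * rho else NULL
  structure(list(
    coefficients = c(intercept = intercept, slope = slope),
    P_prime = P_prime, xi = xi,
    r = stats::cor(pairs$drho_dx, pairs$v),
    rho = rho, K = K,
    pairs = pairs, assay = assay, means = means,
    through_origin = through_origin, lm = fit,
    call = match.call()),
    class = "mech_fit")
}

#' @export
print.mech_fit <- function(x, digits = 3, ...) {
  cat("Pressure-driven boundary motion fit\n")
  cat(sprintf("  %d pairs in %d assay(s); fit through assay averages%s\n",
              nrow(x$pairs), nlevels(x$assay),
              if (x$through_origin) " (through origin)" else ""))
  cat(sprintf("  slope     %s um/h per cells/(mm^2 um)\n",
              format(x$coefficients[["slope"]], digits = digits)))
  cat(sprintf("  r         %s (individual pairs)\n",
              format(x$r, digits = digits)))
  cat(sprintf("  P'(rho)   %s Pa mm^2  (xi = %g Pa s/um^2)\n",
              format(x$P_prime, digits = digits), x$xi))
  if (!is.null(x$K))
    cat(sprintf("  K         %s Pa  (rho = %g cells/mm^2)\n",
                format(x$K, digits = digits), x$rho))
  invisible(x)
}

#' @export
summary.mech_fit <- function(object, ...) {
  s <- summary(object$lm)
  out <- list(fit = object, lm_summary = s)
  class(out) <- "summary.mech_fit"
  out
}

#' @export
print.summary.mech_fit <- function(x, ...) {
  print(x$fit)
  cat("\nLinear fit through assay averages:\n")
  stats::printCoefmat(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.mech_fit <- function(object, ...) object$coefficients

#' @export
predict.mech_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$pairs
  object$coefficients[["intercept"]] +
    object$coefficients[["slope"]] * newdata$drho_dx
}

#' @export
residuals.mech_fit <- function(object, ...) {
  object$pairs$v - predict(object, object$pairs)
}

#' @export
simulate.mech_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd <- stats::sd(residuals(object))
  n <- nrow(object$pairs)
  out <- as.data.frame(replicate(nsim, predict(object, object$pairs) +
                                   stats::rnorm(n, sd = sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.mech_fit <- function(x, ...) {
  graphics::plot(x$pairs$drho_dx, x$pairs$v,
                 pch = 16, cex = 0.6, col = "grey55",
                 xlab = "density gradient at boundary (cells mm^-2 um^-1)",
                 ylab = "boundary velocity (um/h)", ...)
  graphics::points(x$means$drho_dx, x$means$v, pch = 19, cex = 1.3)
  graphics::abline(a = x$coefficients[["intercept"]],
                   b = x$coefficients[["slope"]])
  graphics::legend("topright", bty = "n",
                   legend = c(sprintf("P' = %.3g Pa mm^2", x$P_prime),
                              sprintf("r = %.2f", x$r)))
  invisible(x)
}

#' Bulk modulus from the pressure-density slope
#'
#' With the logarithmic equation of state `P(rho) = K ln(rho / rho_e)`, the
#' local slope is `P'(rho) = K / rho`, so the bulk modulus around the working
#' density is `K = P'(rho) * rho`.
#'
#' @param P_prime pressure-density slope, Pa mm^2.
#' @param rho mean cell density during boundary motion, cells/mm^2 (> 0).
#' @return Bulk modulus in Pa.
#' @examples
#' bulk_modulus(0.5, 3.4e3)   # ~ 2 kPa at one significant figure
#' @export
bulk_modulus <- function(P_prime, rho) {
  if (any(rho <= 0)) stop("`rho` must be positive")
  P_prime * rho
}

#' Logarithmic equation of state
#'
#' Tissue pressure as a function of cell density, `P(rho) = K ln(rho /
#' rho_e)`: zero at the reference density `rho_e`, strictly increasing in
#' `rho`, with density-independent bulk modulus `K`.
#'
#' @param rho cell density, cells/mm^2 (> 0).
#' @param K bulk modulus, Pa (> 0).
#' @param rho_e reference cell density, cells/mm^2 (> 0).
#' @return Pressure in Pa.
#' @export
eos_pressure <- function(rho, K, rho_e) {
  if (any(rho <= 0) || rho_e <= 0 || K <= 0)
    stop("`rho`, `rho_e` and `K` must be positive")
  K * log(rho / rho_e)
}

#' Monolayer stiffness from an effective tensile modulus
#'
#' Converts a monolayer tension-strain modulus Gamma (mN/m) into a bulk
#' stiffness by dividing by the monolayer height: `E = Gamma / h`. With
#' Gamma in mN/m and h in um the result is directly in kPa.
#'
#' @param gamma effective tensile modulus, mN/m.
#' @param height monolayer height, micrometres (> 0).
#' @return Stiffness in kPa.
#' @examples
#' stiffness_from_tension(2.4, 5)   # 0.48 kPa
#' @export
stiffness_from_tension <- function(gamma, height) {
  if (any(height <= 0)) stop("`height` must be positive")
  gamma / height
}
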