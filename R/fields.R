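#' Gridded scalar field movie (PIV-style windows)
#'
#' Holds scalar samples `value(x, y, t)` on a uniform window grid, the form
#' in which PIV velocity fields and window-counted cell densities arrive.
#' The default window size downstream is 88 um, a typical final PIV window.
#' Windows with no tissue are `NA` (missing), never zero-filled.
#'
#' @param x,y window-center coordinates in micrometres (uniformly spaced,
#'   increasing).
#' @param t timepoints in hours, strictly increasing.
#' @param values numeric array `length(y) x length(x) x length(t)`.
#' @param kind `"v_x"` (um/h) or `"density"` (cells/mm^2) or another label.
#' @return An object of class `field_movie`.
#' @export
field_movie <- function(x, y, t, values, kind = "v_x") {
  values <- array(values, dim = c(length(y), length(x), length(t)))
  if (length(t) > 1 && any(diff(t) <= 0))
    stop("timepoints must be strictly increasing")
  check_uniform <- function(v, what) {
    if (length(v) > 1) {
      dv <- diff(v)
      if (any(dv <= 0) || max(dv) - min(dv) > 1e-6 * max(dv))
        stop(what, " window coordinates must be uniformly spaced, increasing")
    }
  }
  check_uniform(x, "x"); check_uniform(y, "y")
  structure(list(x = as.numeric(x), y = as.numeric(y), t = as.numeric(t),
                 values = values, kind = kind),
            class = "field_movie")
}

#' @export
print.field_movie <- function(x, ...) {
  cat(sprintf(
    "<field_movie> kind = %s, %d x %d windows (%g um pitch), %d timepoints\n",
    x$kind, length(x$x), length(x$y),
    if (length(x$x) > 1) diff(x$x[1:2]) else NA, length(x$t)))
  invisible(x)
}

window_pitch <- function(movie) {
  if (length(movie$x) > 1) diff(movie$x[1:2])
  else if (length(movie$y) > 1) diff(movie$y[1:2])
  else stop("cannot infer window pitch from a single window")
}

#' Read and write field tables
#'
#' Field movies are exchanged as delimited text with columns
#' `x_um, y_um, t_h, value` (missing windows written with empty value).
#'
#' @param movie a [field_movie].
#' @param path file path.
#' @param kind value kind attached on read.
#' @return `write_field_table` returns the path invisibly;
#'   `read_field_table` returns a [field_movie].
#' @export
write_field_table <- function(movie, path) {
  df <- data.frame(
    x_um = rep(movie$x, each = length(movie$y), times = length(movie$t)),
    y_um = rep(movie$y, times = length(movie$x) * length(movie$t)),
    t_h = rep(movie$t, each = length(movie$y) * length(movie$x)),
    value = as.vector(movie$values))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_field_table
#' @export
read_field_table <- function(path, kind = "v_x") {
  df <- utils::read.csv(path, na.strings = c("", "NA"))
  need <- c("x_um", "y_um", "t_h", "value")
  if (!all(need %in% names(df)))
    stop("field table must have columns x_um, y_um, t_h, value")
  xs <- sort(unique(df$x_um)); ys <- sort(unique(df$y_um))
  ts <- sort(unique(df$t_h))
  vals <- array(NA_real_, dim = c(length(ys), length(xs), length(ts)))
  vals[cbind(match(df$y_um, ys), match(df$x_um, xs), match(df$t_h, ts))] <-
    df$value
  field_movie(xs, ys, ts, vals, kind = kind)
}

#' Cell density from nuclei centroids by window counting
#'
#' Counts nucleus centroids per window and divides by the window area, the
#' standard way local density is quantified from segmented nuclei. Windows
#' with no points get density 0 (an empty window is an observation, not
#' missing data).
#'
#' @param nuclei data frame with columns `x_um`, `y_um` and optionally `t_h`
#'   (a single timepoint 0 is assumed if absent).
#' @param grid a [tiss_grid] whose spacing is the window size (e.g. 88 um).
#' @return A [field_movie] of kind `"density"`, cells/mm^2.
#' @export
density_from_nuclei <- function(nuclei, grid) {
  if (!all(c("x_um", "y_um") %in% names(nuclei)))
    stop("`nuclei` needs columns x_um, y_um")
  t_h <- if ("t_h" %in% names(nuclei)) nuclei$t_h else rep(0, nrow(nuclei))
  ts <- sort(unique(t_h))
  if (!length(ts)) ts <- 0
  sp <- grid$spacing
  xs <- grid_x(grid); ys <- grid_y(grid)
  xb <- c(xs - sp / 2, xs[length(xs)] + sp / 2)
  yb <- c(ys - sp / 2, ys[length(ys)] + sp / 2)
  area_mm2 <- (sp / 1000)^2
  vals <- array(0, dim = c(grid$ny, grid$nx, length(ts)))
  for (s in seq_along(ts)) {
    sel <- t_h == ts[s] &
      nuclei$x_um >= xb[1] & nuclei$x_um <= xb[length(xb)] &
      nuclei$y_um >= yb[1] & nuclei$y_um <= yb[length(yb)]
    if (!any(sel)) next
    i <- findInterval(nuclei$y_um[sel], yb, rightmost.closed = TRUE)
    j <- findInterval(nuclei$x_um[sel], xb, rightmost.closed = TRUE)
    cnt <- table(factor(i, levels = seq_len(grid$ny)),
                 factor(j, levels = seq_len(grid$nx)))
    vals[, , s] <- as.matrix(cnt) / area_mm2
  }
  field_movie(xs, ys, ts, vals, kind = "density")
}
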