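#' Build a kymograph from a field movie
#'
#' Averages the field along y within a band, per x bin and timepoint,
#' yielding the space x time matrix used to display collision dynamics along
#' the collision axis. Following standard practice, the top and bottom
#' `band_margin` (default 1 mm) of the tissue are excluded before averaging,
#' and the result is smoothed in time with a centered 3-timepoint moving
#' average. Bins with no data (no tissue in any retained window) stay `NA`.
#'
#' @param movie a [field_movie].
#' @param band_margin margin excluded at the top and bottom, micrometres.
#' @param bin x bin width in micrometres; must be a multiple of the window
#'   pitch. Default: one window per bin.
#' @param time_smooth apply the 3-timepoint moving average (default `TRUE`).
#' @return A `kymograph`: list with `x` (bin centers, um), `t` (h), `values`
#'   (`length(x)` x `length(t)` matrix), `kind`, `bin`, `band` (the y range
#'   retained).
#' @export
build_kymograph <- function(movie, band_margin = 1000, bin = NULL,
                            time_smooth = TRUE) {
  ylo <- min(movie$y) + band_margin
  yhi <- max(movie$y) - band_margin
  rows <- which(movie$y >= ylo - 1e-9 & movie$y <= yhi + 1e-9)
  if (!length(rows))
    stop("`band_margin` leaves no rows: margin must be below half the tissue height")
  pitch <- window_pitch(movie)
  if (is.null(bin)) bin <- pitch
  per_bin <- round(bin / pitch)
  if (per_bin < 1 || abs(per_bin * pitch - bin) > 1e-6 * bin)
    stop("`bin` must be a positive multiple of the window pitch (", pitch, " um)")
  nx <- length(movie$x); nt <- length(movie$t)
  nbin <- floor(nx / per_bin)
  grp <- rep(seq_len(nbin), each = per_bin)
  K <- matrix(NA_real_, nbin, nt)
  for (s in seq_len(nt)) {
    slab <- movie$values[rows, , s, drop = FALSE]
    colm <- colMeans(slab, na.rm = TRUE)   # NaN where all-NA
    colm[is.nan(colm)] <- NA_real_
    use <- seq_len(nbin * per_bin)
    K[, s] <- tapply(colm[use], grp, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  xbin <- tapply(movie$x[seq_len(nbin * per_bin)], grp, mean)
  if (time_smooth && nt >= 3) K <- t(apply(K, 1, moving_average3))
  structure(list(x = as.numeric(xbin), t = movie$t, values = K,
                 kind = movie$kind, bin = bin, band = c(ylo, yhi)),
            class = "kymograph")
}

# centered 3-point moving average; NA-aware, endpoints use 2 points
moving_average3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  m <- cbind(c(NA, v[-n]), v, c(v[-1], NA))
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  # keep fully-missing entries missing
  out[is.na(v) & is.na(c(NA, v[-n])) & is.na(c(v[-1], NA))] <- NA_real_
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> kind = %s, %d x-bins (%g um) x %d timepoints\n",
              x$kind, length(x$x), x$bin, length(x$t)))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x$x, x$t, x$values, xlab = "x (um)", ylab = "t (h)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Average kymographs across replicate assays
#'
#' Element-wise mean of aligned kymographs. Replicates are aligned by their
#' initial configuration: `offsets[i]` (um) is subtracted from kymograph i's
#' x axis (rounded to whole bins), e.g. the initial gap midline so that all
#' replicates share x = 0 at the collision site. The averaged extent is set
#' by the median extent of the individual kymographs.
#'
#' @param kymos list of `kymograph` objects with equal bin width and time
#'   base.
#' @param offsets numeric vector of alignment offsets (um), recycled.
#' @return A `kymograph`.
#' @export
average_kymographs <- function(kymos, offsets = 0) {
  if (!length(kymos)) stop("no kymographs given")
  bins <- vapply(kymos, function(k) k$bin, numeric(1))
  if (max(bins) - min(bins) > 1e-9)
    stop("kymographs have incompatible bin widths")
  nts <- vapply(kymos, function(k) length(k$t), integer(1))
  if (length(unique(nts)) != 1 ||
      any(vapply(kymos, function(k) max(abs(k$t - kymos[[1]]$t)),
                 numeric(1)) > 1e-9))
    stop("kymographs have incompatible time bases")
  bin <- bins[1]
  offsets <- rep_len(offsets, length(kymos))
  xs <- lapply(seq_along(kymos), function(i)
    kymos[[i]]$x - round(offsets[i] / bin) * bin)
  lo <- stats::median(vapply(xs, min, numeric(1)))
  hi <- stats::median(vapply(xs, max, numeric(1)))
  xout <- seq(lo, hi, by = bin)
  nt <- length(kymos[[1]]$t)
  acc <- matrix(0, length(xout), nt)
  cnt <- matrix(0L, length(xout), nt)
  for (i in seq_along(kymos)) {
    idx <- round((xs[[i]] - lo) / bin) + 1L
    ok <- idx >= 1L & idx <= length(xout)
    vals <- kymos[[i]]$values[ok, , drop = FALSE]
    rows <- idx[ok]
    fin <- is.finite(vals)
    vals[!fin] <- 0
    acc[rows, ] <- acc[rows, ] + vals
    cnt[rows, ] <- cnt[rows, ] + fin
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  structure(list(x = xout, t = kymos[[1]]$t, values = out,
                 kind = kymos[[1]]$kind, bin = bin,
                 band = kymos[[1]]$band),
            class = "kymograph")
}

#' Center of expansion from a velocity kymograph
#'
#' The center of expansion is the position from which post-fusion tissue flow
#' diverges. Per timepoint, bins with `|v_x|` below the threshold (default
#' 3 um/h) are marked, the largest contiguous run of marked bins is taken,
#' and its midpoint is returned; the trace is `NA` when no bin passes.
#'
#' @param kymo a velocity `kymograph` (um/h).
#' @param threshold stall threshold, um/h.
#' @return Data frame with columns `t` (h) and `x` (um, possibly `NA`).
#' @export
center_of_expansion <- function(kymo, threshold = 3) {
  trace <- vapply(seq_along(kymo$t), function(s) {
    v <- kymo$values[, s]
    pass <- !is.na(v) & abs(v) < threshold
    if (!any(pass)) return(NA_real_)
    r <- rle(pass)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    mean(kymo$x[starts[best]:ends[best]])
  }, numeric(1))
  data.frame(t = kymo$t, x = trace)
}

#' Read and write kymographs as delimited matrices
#'
#' Format: header row `x_um` then the timepoints (h); one row per x bin with
#' the bin center first.
#'
#' @param kymo a `kymograph`.
#' @param path file path.
#' @param kind,bin metadata attached on read.
#' @return `write_kymograph` returns the path invisibly; `read_kymograph`
#'   returns a `kymograph`.
#' @export
write_kymograph <- function(kymo, path) {
  m <- cbind(x_um = kymo$x, kymo$values)
  colnames(m) <- c("x_um", sprintf("%.10g", kymo$t))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path, kind = "v_x", bin = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  x <- df[[1]]
  t <- as.numeric(names(df)[-1])
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- NULL
  if (is.null(bin)) bin <- if (length(x) > 1) diff(x[1:2]) else NA_real_
  structure(list(x = x, t = t, values = vals, kind = kind, bin = bin,
                 band = NULL),
            class = "kymograph")
}
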