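#' Physical sampling grid
#'
#' A `tiss_grid` ties a raster to physical coordinates. All public interfaces
#' in this package work in micrometres; pixels are an internal representation.
#' Pixel `(i, j)` (row `i`, column `j`, 1-based) has its center at
#' `origin + ((j - 1) * spacing, (i - 1) * spacing)`, with `y` increasing
#' downward (row-major image convention).
#'
#' @param spacing pixel size, micrometres per pixel (> 0).
#' @param nx,ny number of pixels along x and y. Alternatively give `world`.
#' @param world optional `c(width, height)` extent in micrometres; `nx`, `ny`
#'   are then chosen to cover it and `origin` defaults to `spacing / 2` so the
#'   pixel cells tile `[0, width] x [0, height]`.
#' @param origin physical coordinate `c(x, y)` of the first pixel center.
#' @return An object of class `tiss_grid`.
#' @examples
#' g <- tiss_grid(10, world = c(2000, 1000))
#' g$nx
#' @export
tiss_grid <- function(spacing, nx = NULL, ny = NULL, world = NULL,
                      origin = NULL) {
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("`spacing` must be a single positive number (micrometres per pixel)")
  if (is.null(nx) || is.null(ny)) {
    if (is.null(world) || length(world) != 2L || any(world <= 0))
      stop("supply `nx` and `ny`, or a strictly positive `world = c(width, height)`")
    nx <- as.integer(ceiling(world[1] / spacing - 1e-9))
    ny <- as.integer(ceiling(world[2] / spacing - 1e-9))
    if (is.null(origin)) origin <- c(spacing / 2, spacing / 2)
  }
  if (is.null(origin)) origin <- c(0, 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 1L || ny < 1L) stop("grid must have at least one pixel")
  structure(list(spacing = spacing, nx = nx, ny = ny,
                 origin = as.numeric(origin)),
            class = "tiss_grid")
}

#' @export
print.tiss_grid <- function(x, ...) {
  cat(sprintf("<tiss_grid> %d x %d px at %g um/px, origin (%g, %g) um\n",
              x$nx, x$ny, x$spacing, x$origin[1], x$origin[2]))
  invisible(x)
}

# pixel-center coordinate vectors, micrometres
grid_x <- function(grid) grid$origin[1] + (seq_len(grid$nx) - 1L) * grid$spacing
grid_y <- function(grid) grid$origin[2] + (seq_len(grid$ny) - 1L) * grid$spacing

#' Integer-labelled occupancy field
#'
#' A `label_field` is an `ny x nx` integer matrix over a [tiss_grid]:
#' 0 marks free space, a positive integer `k` marks pixels occupied by tissue
#' `k`. Label regions are pairwise disjoint by construction (a pixel holds at
#' most one label).
#'
#' @param labels integer matrix, `ny x nx`, values >= 0.
#' @param grid a [tiss_grid] whose dimensions match `labels`.
#' @param time timepoint in hours attached to the field.
#' @return An object of class `label_field`.
#' @export
label_field <- function(labels, grid, time = 0) {
  if (!inherits(grid, "tiss_grid")) stop("`grid` must be a tiss_grid")
  labels <- as.matrix(labels)
  if (nrow(labels) != grid$ny || ncol(labels) != grid$nx)
    stop(sprintf("labels must be %d x %d to match the grid", grid$ny, grid$nx))
  if (anyNA(labels) || any(labels < 0))
    stop("labels must be non-negative integers (0 = free space)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, grid = grid, time = time),
            class = "label_field")
}

#' @export
print.label_field <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("<label_field> t = %g h, %d x %d px at %g um/px, tissues: %s\n",
              x$time, x$grid$nx, x$grid$ny, x$grid$spacing,
              if (length(ids)) paste(ids, collapse = ", ") else "none"))
  invisible(x)
}

#' Occupied area of one tissue
#'
#' @param field a [label_field].
#' @param id tissue id.
#' @return Area in square micrometres.
#' @export
label_area <- function(field, id) {
  sum(field$labels == id) * field$grid$spacing^2
}

#' @describeIn label_field display a label field as an image, free space white.
#' @param x a `label_field`.
#' @param col colours for the tissue ids present.
#' @param ... passed to [graphics::image].
#' @export
plot.label_field <- function(x, col = NULL, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  if (is.null(col))
    col <- grDevices::hcl.colors(max(length(ids), 2L), "Dark 3")[seq_along(ids)]
  pal <- c("white", col)
  z <- matrix(match(x$labels, c(0L, ids)), nrow(x$labels))
  # transpose so x runs along the horizontal axis, y downward
  graphics::image(grid_x(x$grid), grid_y(x$grid), t(z)[, rev(seq_len(nrow(z)))],
                  col = pal, xlab = "x (um)", ylab = "y (um)",
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Movie of label fields
#'
#' Ordered label fields at strictly increasing times, sharing one grid.
#' For simulator output the pinning rule holds: once a pixel is nonzero its
#' label never changes in later frames.
#'
#' @param fields list of [label_field] objects on a common grid.
#' @param speeds named numeric, per-tissue normal speed in um/h.
#' @return An object of class `label_movie`.
#' @export
label_movie <- function(fields, speeds = NULL) {
  if (!length(fields)) stop("empty movie")
  times <- vapply(fields, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(fields = fields, times = times, grid = fields[[1]]$grid,
                 speeds = speeds),
            class = "label_movie")
}

#' @export
print.label_movie <- function(x, ...) {
  cat(sprintf("<label_movie> %d frames, t = %g..%g h, %d x %d px at %g um/px\n",
              length(x$fields), min(x$times), max(x$times),
              x$grid$nx, x$grid$ny, x$grid$spacing))
  invisible(x)
}

#' @export
`[.label_movie` <- function(x, i) x$fields[[i]]

#' @export
length.label_movie <- function(x) length(x$fields)

#' Read and write label images as 16-bit TIFF
#'
#' Label fields are stored as 16-bit single-page TIFF, movies as multi-page
#' TIFF with one page per timepoint. Physical metadata (pixel spacing,
#' origin, frame times in hours) travels in a small YAML sidecar file at
#' `<path>.meta`, written and read automatically; without the sidecar the
#' pixels are still read, with a 1 um/px grid and frame index as time.
#'
#' @param x a [label_field] or [label_movie].
#' @param path file path.
#' @return `write_label_tiff` returns `path` invisibly; `read_label_tiff`
#'   returns a [label_field] (single page) or [label_movie] (multi-page).
#' @export
write_label_tiff <- function(x, path) {
  if (inherits(x, "label_field")) x <- label_movie(list(x))
  if (!inherits(x, "label_movie")) stop("need a label_field or label_movie")
  if (max(vapply(x$fields, function(f) max(f$labels), integer(1))) > 65535L)
    stop("labels exceed 16-bit range")
  pages <- lapply(x$fields, function(f) f$labels / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(spacing_um = x$grid$spacing,
               origin_um = as.numeric(x$grid$origin),
               times_h = as.numeric(x$times))
  writeLines(yaml::as.yaml(meta), paste0(path, ".meta"))
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  spacing <- 1; origin <- c(0.5, 0.5); times <- seq_along(pages) - 1
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    spacing <- meta$spacing_um
    origin <- as.numeric(meta$origin_um)
    times <- as.numeric(meta$times_h)
  }
  grid <- tiss_grid(spacing, nx = ncol(pages[[1]]), ny = nrow(pages[[1]]),
                    origin = origin)
  fields <- lapply(seq_along(pages), function(i)
    label_field(round(pages[[i]] * 65535), grid, time = times[i]))
  if (length(fields) == 1L) fields[[1]] else label_movie(fields)
}
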