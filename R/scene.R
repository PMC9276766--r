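#' Tissue seed shapes
#'
#' Initial tissue footprints are described geometrically, in micrometres.
#' `shape_rectangle`, `shape_circle`, `shape_ellipse` and `shape_polygon`
#' build the standard footprints; `shape_mask` wraps a raster mask (any
#' nonzero entry is inside) with its own pixel spacing and origin, e.g. a
#' footprint traced from a micrograph.
#'
#' @param center `c(x, y)` in micrometres.
#' @param width,height rectangle side lengths, micrometres.
#' @param angle rotation in degrees, counterclockwise about the center.
#' @param radius circle radius, micrometres.
#' @param a,b ellipse semi-axes along the (rotated) x and y directions.
#' @param vertices two-column matrix (or list of `c(x, y)`) of polygon
#'   vertices in order; the polygon must be simple (non-self-intersecting).
#' @param mask numeric/logical matrix; nonzero means inside.
#' @param spacing,origin raster geometry of `mask` (see [tiss_grid]).
#' @return A shape object (list with class `tiss_shape`).
#' @export
shape_rectangle <- function(center, width, height, angle = 0) {
  stopifnot(length(center) == 2, width > 0, height > 0)
  new_shape("rectangle", center = as.numeric(center), width = width,
            height = height, angle = angle)
}

#' @rdname shape_rectangle
#' @export
shape_circle <- function(center, radius) {
  stopifnot(length(center) == 2, radius > 0)
  new_shape("circle", center = as.numeric(center), radius = radius)
}

#' @rdname shape_rectangle
#' @export
shape_ellipse <- function(center, a, b, angle = 0) {
  stopifnot(length(center) == 2, a > 0, b > 0)
  new_shape("ellipse", center = as.numeric(center), a = a, b = b, angle = angle)
}

#' @rdname shape_rectangle
#' @export
shape_polygon <- function(vertices) {
  if (is.list(vertices)) vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("polygon needs at least 3 (x, y) vertices")
  if (!polygon_is_simple(vertices))
    stop("polygon is self-intersecting; footprints must be simple polygons")
  new_shape("polygon", vertices = vertices)
}

#' @rdname shape_rectangle
#' @export
shape_mask <- function(mask, spacing, origin = c(spacing / 2, spacing / 2)) {
  mask <- as.matrix(mask) != 0
  new_shape("mask", mask = mask, spacing = spacing, origin = as.numeric(origin))
}

new_shape <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "tiss_shape")
}

# membership test for vectorized pixel centers (x, y in micrometres)
shape_contains <- function(shape, x, y) {
  switch(shape$kind,
    rectangle = {
      th <- -shape$angle * pi / 180
      dx <- x - shape$center[1]; dy <- y - shape$center[2]
      u <- dx * cos(th) - dy * sin(th)
      v <- dx * sin(th) + dy * cos(th)
      abs(u) <= shape$width / 2 & abs(v) <= shape$height / 2
    },
    circle = (x - shape$center[1])^2 + (y - shape$center[2])^2 <=
      shape$radius^2,
    ellipse = {
      th <- -shape$angle * pi / 180
      dx <- x - shape$center[1]; dy <- y - shape$center[2]
      u <- dx * cos(th) - dy * sin(th)
      v <- dx * sin(th) + dy * cos(th)
      (u / shape$a)^2 + (v / shape$b)^2 <= 1
    },
    polygon = point_in_polygon(shape$vertices, x, y),
    mask = {
      j <- round((x - shape$origin[1]) / shape$spacing) + 1
      i <- round((y - shape$origin[2]) / shape$spacing) + 1
      ok <- i >= 1 & i <= nrow(shape$mask) & j >= 1 & j <= ncol(shape$mask)
      inside <- logical(length(x))
      inside[ok] <- shape$mask[cbind(i[ok], j[ok])]
      inside
    },
    stop("unknown shape kind: ", shape$kind)
  )
}

# even-odd ray casting, vectorized over query points
point_in_polygon <- function(verts, x, y) {
  n <- nrow(verts)
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip segments sharing a vertex
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

shape_bbox <- function(shape) {
  switch(shape$kind,
    rectangle = {
      th <- shape$angle * pi / 180
      hw <- abs(cos(th)) * shape$width / 2 + abs(sin(th)) * shape$height / 2
      hh <- abs(sin(th)) * shape$width / 2 + abs(cos(th)) * shape$height / 2
      c(shape$center[1] - hw, shape$center[2] - hh,
        shape$center[1] + hw, shape$center[2] + hh)
    },
    circle = c(shape$center - shape$radius, shape$center + shape$radius),
    ellipse = {
      r <- max(shape$a, shape$b)
      c(shape$center - r, shape$center + r)
    },
    polygon = c(min(shape$vertices[, 1]), min(shape$vertices[, 2]),
                max(shape$vertices[, 1]), max(shape$vertices[, 2])),
    mask = c(shape$origin - shape$spacing / 2,
             shape$origin[1] + (ncol(shape$mask) - 0.5) * shape$spacing,
             shape$origin[2] + (nrow(shape$mask) - 0.5) * shape$spacing)
  )
}

shape_is_convex <- function(shape) {
  switch(shape$kind,
    rectangle = TRUE, circle = TRUE, ellipse = TRUE,
    polygon = {
      v <- shape$vertices; n <- nrow(v)
      cr <- numeric(n)
      for (i in seq_len(n)) {
        a <- v[i, ]; b <- v[i %% n + 1, ]; c <- v[(i + 1) %% n + 1, ]
        cr[i] <- (b[1] - a[1]) * (c[2] - b[2]) - (b[2] - a[2]) * (c[1] - b[1])
      }
      all(cr >= 0) || all(cr <= 0)
    },
    mask = FALSE
  )
}

#' Tissue seed
#'
#' One tissue in a [scene]: an id, an initial footprint, a normal expansion
#' speed and optional seeding density and colour tag.
#'
#' @param id unique positive integer identifying the tissue.
#' @param shape a footprint from [shape_rectangle] and friends.
#' @param speed outward normal edge speed v_n, um/h (>= 0); `NULL` falls back
#'   to the scene default.
#' @param density optional initial cell density, cells/mm^2.
#' @param color optional colour tag used for plots and dye bookkeeping.
#' @return An object of class `tissue_seed`.
#' @export
tissue_seed <- function(id, shape, speed = NULL, density = NULL, color = NULL) {
  if (length(id) != 1 || is.na(id) || id != round(id) || id < 1)
    stop("tissue `id` must be a positive integer")
  if (!inherits(shape, "tiss_shape")) stop("`shape` must be a tiss_shape")
  if (!is.null(speed) && (length(speed) != 1 || speed < 0))
    stop("`speed` must be a single non-negative number (um/h)")
  if (!is.null(density) && (length(density) != 1 || density <= 0))
    stop("`density` must be a single positive number (cells/mm^2)")
  structure(list(id = as.integer(id), shape = shape, speed = speed,
                 density = density, color = color),
            class = "tissue_seed")
}

#' Scene: initial configuration of a collision or tessellation assay
#'
#' A scene lists tissue seeds over a rectangular world. Seeds must not
#' overlap (tissues are grown from disjoint footprints); overlap is checked
#' on a fine validation raster. Tissues missing a speed inherit
#' `default_speed`; the package default of 29.5 um/h is the measured normal
#' expansion speed of MDCK monolayers.
#'
#' @param tissues list of [tissue_seed] objects.
#' @param world `c(width, height)` of the world in micrometres.
#' @param default_speed fallback normal speed, um/h.
#' @return An object of class `scene`.
#' @examples
#' sc <- scene(list(
#'   tissue_seed(1, shape_rectangle(c(1000, 1500), 1000, 1000)),
#'   tissue_seed(2, shape_rectangle(c(2500, 1500), 1000, 1000))
#' ), world = c(4000, 3000))
#' speeds(sc)
#' @export
scene <- function(tissues = list(), world, default_speed = 29.5) {
  if (length(world) != 2 || any(!is.finite(world)) || any(world <= 0))
    stop("`world` must be c(width, height), strictly positive, in micrometres")
  if (default_speed < 0) stop("`default_speed` must be >= 0")
  if (!all(vapply(tissues, inherits, logical(1), "tissue_seed")))
    stop("`tissues` must be a list of tissue_seed objects")
  ids <- vapply(tissues, function(t) t$id, integer(1))
  if (anyDuplicated(ids))
    stop("tissue ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sc <- structure(list(tissues = tissues, world = as.numeric(world),
                       default_speed = default_speed),
                  class = "scene")
  check_seed_overlap(sc)
  sc
}

# pairwise-disjointness check on a validation raster (~512 px across),
# with a bounding-box prefilter
check_seed_overlap <- function(sc) {
  n <- length(sc$tissues)
  if (n < 2) return(invisible(sc))
  spacing <- max(sc$world) / 512
  grid <- tiss_grid(spacing, world = sc$world)
  xs <- grid_x(grid); ys <- grid_y(grid)
  X <- matrix(xs, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(ys, grid$ny, grid$nx)
  bb <- lapply(sc$tissues, function(t) shape_bbox(t$shape))
  masks <- vector("list", n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bb[[i]][3] < bb[[j]][1] || bb[[j]][3] < bb[[i]][1] ||
          bb[[i]][4] < bb[[j]][2] || bb[[j]][4] < bb[[i]][2]) next
      if (is.null(masks[[i]]))
        masks[[i]] <- shape_contains(sc$tissues[[i]]$shape, X, Y)
      if (is.null(masks[[j]]))
        masks[[j]] <- shape_contains(sc$tissues[[j]]$shape, X, Y)
      if (any(masks[[i]] & masks[[j]]))
        stop(sprintf("initial footprints of tissues %d and %d overlap",
                     sc$tissues[[i]]$id, sc$tissues[[j]]$id))
    }
  }
  invisible(sc)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %g x %g um world, %d tissue(s), default v_n = %g um/h\n",
              x$world[1], x$world[2], length(x$tissues), x$default_speed))
  for (t in x$tissues)
    cat(sprintf("  tissue %d: %s, v_n = %g um/h%s\n", t$id, t$shape$kind,
                if (is.null(t$speed)) x$default_speed else t$speed,
                if (is.null(t$density)) ""
                else sprintf(", rho0 = %g cells/mm^2", t$density)))
  invisible(x)
}

#' Per-tissue normal speeds of a scene
#'
#' @param sc a [scene].
#' @return Named numeric vector of v_n (um/h), names are tissue ids.
#' @export
speeds <- function(sc) {
  stats::setNames(
    vapply(sc$tissues, function(t)
      if (is.null(t$speed)) sc$default_speed else t$speed, numeric(1)),
    vapply(sc$tissues, function(t) t$id, integer(1)))
}

#' Load a scene description file
#'
#' Scene files are YAML. Schema:
#' ```yaml
#' world: {width: 4000, height: 3000}   # micrometres
#' default_speed: 29.5                  # um/h, optional
#' tissues:
#'   - id: 1
#'     shape: {kind: rectangle, center: [1000, 1500], width: 1000,
#'             height: 1000, angle: 0}
#'     speed: 29.5        # optional, falls back to default_speed
#'     density: 2600      # optional, cells/mm^2
#'     color: "#e41a1c"   # optional
#'   - id: 2
#'     shape: {kind: circle, center: [3000, 1500], radius: 500}
#' ```
#' Shape kinds: `rectangle` (center, width, height, angle), `circle`
#' (center, radius), `ellipse` (center, a, b, angle), `polygon`
#' (vertices: list of `[x, y]`), `mask` (path to a TIFF whose nonzero pixels
#' are the footprint, plus spacing and optional origin). Example scenes ship
#' in `system.file("extdata", package = "tissellate")`.
#'
#' @param file path to a scene file, or a literal YAML string.
#' @return A validated [scene].
#' @export
load_scene <- function(file) {
  doc <- if (is.character(file) && length(file) == 1 && !grepl("\n", file) &&
             file.exists(file)) yaml::read_yaml(file)
         else yaml::yaml.load(file)
  if (is.null(doc$world))
    stop("scene file must have a `world: {width, height}` entry")
  world <- c(doc$world$width, doc$world$height)
  default_speed <- if (is.null(doc$default_speed)) 29.5 else doc$default_speed
  base <- if (is.character(file) && file.exists(file)) dirname(file) else "."
  tissues <- lapply(doc$tissues, function(t) {
    if (is.null(t$id) || is.null(t$shape))
      stop("each tissue needs `id` and `shape`")
    tissue_seed(t$id, shape_from_list(t$shape, base), speed = t$speed,
                density = t$density, color = t$color)
  })
  scene(tissues, world = world, default_speed = default_speed)
}

shape_from_list <- function(s, base = ".") {
  if (is.null(s$kind)) stop("shape needs a `kind`")
  switch(s$kind,
    rectangle = shape_rectangle(unlist(s$center), s$width, s$height,
                                angle = s$angle %||% 0),
    circle = shape_circle(unlist(s$center), s$radius),
    ellipse = shape_ellipse(unlist(s$center), s$a, s$b, angle = s$angle %||% 0),
    polygon = shape_polygon(do.call(rbind, lapply(s$vertices, unlist))),
    mask = {
      m <- if (!is.null(s$path)) {
        p <- if (file.exists(s$path)) s$path else file.path(base, s$path)
        round(tiff::readTIFF(p) * 65535)
      } else do.call(rbind, lapply(s$mask, unlist))
      shape_mask(m, spacing = s$spacing,
                 origin = if (is.null(s$origin)) c(s$spacing / 2, s$spacing / 2)
                          else unlist(s$origin))
    },
    stop("unknown shape kind: ", s$kind)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a scene onto a grid
#'
#' A pixel is labelled `k` iff its center lies inside tissue `k`'s footprint;
#' all other pixels are 0 (free space). Deterministic: the same scene and
#' grid always give a bit-identical field.
#'
#' @param sc a [scene].
#' @param grid a [tiss_grid] covering the scene's world extent.
#' @return A [label_field] at time 0.
#' @export
rasterize <- function(sc, grid) {
  if (!inherits(sc, "scene")) stop("`sc` must be a scene")
  if (!inherits(grid, "tiss_grid")) stop("`grid` must be a tiss_grid")
  cover_x <- grid$origin[1] + (grid$nx - 0.5) * grid$spacing
  cover_y <- grid$origin[2] + (grid$ny - 0.5) * grid$spacing
  if (cover_x < sc$world[1] - 1e-6 || cover_y < sc$world[2] - 1e-6)
    stop("grid does not cover the scene's world extent")
  lab <- matrix(0L, grid$ny, grid$nx)
  xs <- grid_x(grid); ys <- grid_y(grid)
  X <- matrix(xs, grid$ny, grid$nx, byrow = TRUE)
  Y <- matrix(ys, grid$ny, grid$nx)
  for (t in sc$tissues) {
    inside <- shape_contains(t$shape, X, Y)
    lab[inside] <- t$id   # seeds are disjoint, so order is immaterial
  }
  label_field(lab, grid, time = 0)
}
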