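#' Extract the boundary polyline between two tissues
#'
#' Collects the midpoints of all 4-adjacent pixel pairs carrying the two
#' labels (a sub-pixel interface sample) and chains them into an ordered
#' polyline by greedy nearest-neighbour traversal from an extremal point.
#' Deterministic for a given field.
#'
#' @param field a [label_field].
#' @param idA,idB the two tissue ids.
#' @return A `boundary_curve`: data frame with columns `x`, `y` (um) in curve
#'   order, with attributes `pair`, `time` and `spacing`. Zero rows when the
#'   labels are nowhere adjacent.
#' @export
extract_boundary <- function(field, idA, idB) {
  lab <- field$labels
  sp <- field$grid$spacing
  xs <- grid_x(field$grid); ys <- grid_y(field$grid)
  ny <- nrow(lab); nx <- ncol(lab)
  A <- lab == idA; B <- lab == idB
  pts_x <- numeric(0); pts_y <- numeric(0)
  # horizontal neighbours (same row, adjacent columns)
  h <- (A[, -nx] & B[, -1]) | (B[, -nx] & A[, -1])
  if (any(h)) {
    w <- which(h, arr.ind = TRUE)
    pts_x <- c(pts_x, xs[w[, 2]] + sp / 2)
    pts_y <- c(pts_y, ys[w[, 1]])
  }
  # vertical neighbours
  v <- (A[-ny, ] & B[-1, ]) | (B[-ny, ] & A[-1, ])
  if (any(v)) {
    w <- which(v, arr.ind = TRUE)
    pts_x <- c(pts_x, xs[w[, 2]])
    pts_y <- c(pts_y, ys[w[, 1]] + sp / 2)
  }
  ord <- chain_points(pts_x, pts_y)
  out <- data.frame(x = pts_x[ord], y = pts_y[ord])
  structure(out, class = c("boundary_curve", "data.frame"),
            pair = c(idA, idB), time = field$time, spacing = sp)
}

# order scattered interface points into a path: start from the extremal point
# (min y, then min x), repeatedly hop to the nearest unvisited point
chain_points <- function(x, y) {
  n <- length(x)
  if (n <= 2) return(seq_len(n))
  ord <- integer(n)
  visited <- logical(n)
  cur <- order(y, x)[1]
  for (s in seq_len(n)) {
    ord[s] <- cur
    visited[cur] <- TRUE
    if (s == n) break
    d2 <- (x - x[cur])^2 + (y - y[cur])^2
    d2[visited] <- Inf
    cur <- which.min(d2)
  }
  ord
}

#' @export
print.boundary_curve <- function(x, ...) {
  p <- attr(x, "pair")
  cat(sprintf("<boundary_curve> tissues %d|%d, %d vertices, t = %g h\n",
              p[1], p[2], nrow(x), attr(x, "time")))
  invisible(x)
}

resample_curve <- function(curve, step) {
  dx <- diff(curve$x); dy <- diff(curve$y)
  s <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  if (s[length(s)] <= 0) return(curve)
  sq <- seq(0, s[length(s)], by = step)
  data.frame(x = stats::approx(s, curve$x, sq)$y,
             y = stats::approx(s, curve$y, sq)$y)
}

#' Boundary roughness
#'
#' Root-mean-square deviation of the boundary's transverse coordinate from
#' its mean line, after resampling the polyline at uniform arc length. For a
#' collision along x, the boundary runs transverse to x and its roughness is
#' the RMS of the vertices' x coordinates about their mean. Translation- and
#' mirror-invariant; scales linearly with the perturbation amplitude. If the
#' boundary doubles back (is multivalued along its run direction) the value
#' is still computed on the arc-length-resampled residuals and the result
#' carries the attribute `multivalued = TRUE`.
#'
#' @param curve a `boundary_curve` from [extract_boundary] (any data frame
#'   with `x`, `y` columns works).
#' @param axis the collision axis, `"x"` or `"y"`: the direction along which
#'   the tissues collided, i.e. the coordinate whose scatter is measured.
#' @param resample arc-length resampling step in micrometres.
#' @return Roughness in micrometres.
#' @export
boundary_roughness <- function(curve, axis = c("x", "y"), resample = 10) {
  axis <- match.arg(axis)
  if (!nrow(curve)) stop("empty boundary curve")
  rc <- resample_curve(curve, resample)
  coord <- if (axis == "x") rc$x else rc$y
  run <- if (axis == "x") rc$y else rc$x
  out <- sqrt(mean((coord - mean(coord))^2))
  dr <- diff(run)
  if (length(dr) && !(all(dr >= 0) || all(dr <= 0)))
    attr(out, "multivalued") <- TRUE
  out
}

#' Mean distance between a predicted and an observed boundary
#'
#' Symmetrized mean nearest-point distance: the mean over vertices of one
#' curve of the distance to the nearest vertex of the other, averaged over
#' both directions. Zero iff the curves coincide; symmetric in its arguments.
#'
#' @param predicted,observed boundary curves (data frames with `x`, `y`).
#' @return Mean error in micrometres.
#' @export
boundary_prediction_error <- function(predicted, observed) {
  if (!nrow(predicted) || !nrow(observed))
    stop("both curves must be non-empty")
  one_way <- function(a, b) {
    d <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    mean(sqrt(apply(d, 1, min)))
  }
  (one_way(predicted, observed) + one_way(observed, predicted)) / 2
}

#' Locate tri-tissue junction points
#'
#' Scans all 2x2 pixel neighbourhoods for sites containing three or more
#' distinct nonzero labels, clusters the sites (8-connectivity) and reports
#' each cluster's centroid as one junction. Deterministic and robust to
#' resolution.
#'
#' @param field a [label_field] with at least 3 labels (fewer labels simply
#'   yield an empty result).
#' @return Data frame with columns `x`, `y` (um), `id1`, `id2`, `id3` (the
#'   three incident tissue ids, ascending) and `n_sites` (cluster size).
#' @export
find_trijunctions <- function(field) {
  lab <- field$labels
  ny <- nrow(lab); nx <- ncol(lab)
  empty <- data.frame(x = numeric(0), y = numeric(0), id1 = integer(0),
                      id2 = integer(0), id3 = integer(0), n_sites = integer(0))
  if (ny < 2 || nx < 2) return(empty)
  a <- lab[-ny, -nx]; b <- lab[-1, -nx]; c_ <- lab[-ny, -1]; d <- lab[-1, -1]
  distinct <- function(w, x, y, z) {
    n <- (w > 0) + ((x > 0) & (x != w)) +
      ((y > 0) & (y != w) & (y != x)) +
      ((z > 0) & (z != w) & (z != x) & (z != y))
    n
  }
  tri <- distinct(a, b, c_, d) >= 3
  if (!any(tri)) return(empty)
  sites <- which(tri, arr.ind = TRUE)  # top-left corner of the 2x2 block
  comp <- cluster_sites(sites)
  xs <- grid_x(field$grid); ys <- grid_y(field$grid)
  sp <- field$grid$spacing
  out <- lapply(split(seq_len(nrow(sites)), comp), function(ii) {
    s <- sites[ii, , drop = FALSE]
    cells <- unique(c(lab[cbind(s[, 1], s[, 2])], lab[cbind(s[, 1] + 1, s[, 2])],
                      lab[cbind(s[, 1], s[, 2] + 1)],
                      lab[cbind(s[, 1] + 1, s[, 2] + 1)]))
    ids <- sort(setdiff(cells, 0L))[1:3]
    data.frame(x = mean(xs[s[, 2]]) + sp / 2, y = mean(ys[s[, 1]]) + sp / 2,
               id1 = ids[1], id2 = ids[2], id3 = ids[3], n_sites = nrow(s))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# 8-connected components of integer (row, col) sites; small n, simple BFS
cluster_sites <- function(sites) {
  n <- nrow(sites)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      nb <- which(comp == 0L &
                    abs(sites[, 1] - sites[i, 1]) <= 1 &
                    abs(sites[, 2] - sites[i, 2]) <= 1)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Track a tissue-tissue boundary through a movie
#'
#' For each frame, extracts the boundary between the two labels and records
#' its mean position along the collision axis. The trace is defined from the
#' fusion time (first frame in which the labels are adjacent) onward; earlier
#' entries are `NA`. The fusion location is the trace's first defined value,
#' and `x0` is the initial gap midline (midpoint between the facing tissue
#' edges in the first frame).
#'
#' @param movie a [label_movie].
#' @param idA,idB tissue ids (defaults: the two lowest ids present).
#' @param axis collision axis, `"x"` or `"y"`.
#' @return A `boundary_trace`: data frame with columns `t` (h) and `x` (um,
#'   mean boundary position), with attributes `x0`, `fusion_time`,
#'   `fusion_x`.
#' @export
boundary_trace <- function(movie, idA = NULL, idB = NULL, axis = "x") {
  ids <- setdiff(sort(unique(as.vector(movie$fields[[1]]$labels))), 0L)
  if (is.null(idA)) idA <- ids[1]
  if (is.null(idB)) idB <- ids[2]
  pos <- vapply(movie$fields, function(f) {
    bc <- extract_boundary(f, idA, idB)
    if (!nrow(bc)) return(NA_real_)
    if (axis == "x") mean(bc$x) else mean(bc$y)
  }, numeric(1))
  lab0 <- movie$fields[[1]]$labels
  coord <- if (axis == "x") grid_x(movie$grid) else grid_y(movie$grid)
  proj <- function(id) {
    w <- if (axis == "x") which(lab0 == id, arr.ind = TRUE)[, 2]
         else which(lab0 == id, arr.ind = TRUE)[, 1]
    range(coord[w])
  }
  rA <- proj(idA); rB <- proj(idB)
  x0 <- if (rA[2] < rB[1]) (rA[2] + rB[1]) / 2 else (rB[2] + rA[1]) / 2
  fused <- which(!is.na(pos))
  structure(data.frame(t = movie$times, x = pos),
            class = c("boundary_trace", "data.frame"),
            x0 = x0,
            fusion_time = if (length(fused)) movie$times[fused[1]] else NA,
            fusion_x = if (length(fused)) pos[fused[1]] else NA,
            pair = c(idA, idB))
}

#' @export
print.boundary_trace <- function(x, ...) {
  cat(sprintf(
    "<boundary_trace> tissues %d|%d, fusion at t = %g h, x = %g um (x0 = %g)\n",
    attr(x, "pair")[1], attr(x, "pair")[2], attr(x, "fusion_time"),
    attr(x, "fusion_x"), attr(x, "x0")))
  invisible(x)
}

#' Write boundary polylines of a movie to delimited text
#'
#' One row per vertex: `pair_a, pair_b, t_h, order, x_um, y_um`.
#'
#' @param movie a [label_movie].
#' @param path output file.
#' @param pairs two-column matrix of id pairs, or `"all"` for every adjacent
#'   pair in the final frame.
#' @return The path, invisibly.
#' @export
write_boundaries_csv <- function(movie, path, pairs = "all") {
  ids <- setdiff(sort(unique(as.vector(
    movie$fields[[length(movie)]]$labels))), 0L)
  if (identical(pairs, "all")) {
    pairs <- t(utils::combn(ids, 2))
  }
  rows <- list()
  for (f in movie$fields) {
    for (r in seq_len(nrow(pairs))) {
      bc <- extract_boundary(f, pairs[r, 1], pairs[r, 2])
      if (!nrow(bc)) next
      rows[[length(rows) + 1]] <- data.frame(
        pair_a = pairs[r, 1], pair_b = pairs[r, 2], t_h = f$time,
        order = seq_len(nrow(bc)), x_um = bc$x, y_um = bc$y)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pair_a = integer(0), pair_b = integer(0), t_h = numeric(0),
               order = integer(0), x_um = numeric(0), y_um = numeric(0))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
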