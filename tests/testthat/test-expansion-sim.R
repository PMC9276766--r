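test_that("step_fronts respects speeds, pinning and the CFL condition", {
  sc <- control_pair_scene(world = c(1500, 800), width = 400, gap = 300)
  g <- tiss_grid(10, world = c(1500, 800))
  f0 <- rasterize(sc, g)

  # zero speeds: output identical to input
  f1 <- step_fronts(f0, c(`1` = 0, `2` = 0), dt = 1)
  expect_identical(f1$labels, f0$labels)

  # CFL violation is rejected with guidance
  expect_error(step_fronts(f0, c(`1` = 29.5, `2` = 29.5), dt = 1), "dt")

  # stepping and fractional carry: ~10 um advance per 20 min at 29.5 um/h
  f <- f0
  for (i in 1:12) f <- step_fronts(f, c(`1` = 29.5, `2` = 29.5), dt = 1 / 3)
  expect_equal(f$time, 4)
  grown <- (label_area(f, 1) - label_area(f0, 1)) / label_area(f0, 1)
  expect_gt(grown, 0.2)
})

test_that("a free circle expands at its normal speed", {
  world <- c(1800, 1800)
  sc <- scene(list(tissue_seed(1, shape_circle(c(900, 900), 500))),
              world = world)
  mv <- simulate(sc, grid = tiss_grid(10, world = world), t_end = 10, dt = 1 / 3)
  # R(t) = R0 + v t: effective radius after 10 h within one pixel of 795 um
  r_end <- sqrt(label_area(mv[length(mv)], 1) / pi)
  expect_lt(abs(r_end - 795), 10)
  expect_lt(abs(free_edge_speed(mv, 1) - 29.5), 0.3)
  expect_lt(abs(free_edge_speed(mv, 1, "displacement") - 29.5), 0.3)
})

test_that("free-edge speed is shape independent and handles edge cases", {
  world <- c(1600, 1600)
  sq <- scene(list(tissue_seed(1, shape_rectangle(c(800, 800), 1000, 1000),
                               speed = 20)), world = world)
  mv <- simulate(sq, grid = tiss_grid(10, world = world), t_end = 10, dt = 1 / 3)
  expect_lt(abs(free_edge_speed(mv, 1, "displacement") - 20), 0.5)

  # speed-0 tissue measures 0
  still <- scene(list(tissue_seed(1, shape_circle(c(400, 400), 200), speed = 0)),
                 world = c(800, 800))
  mv0 <- simulate(still, grid = tiss_grid(10, world = c(800, 800)),
                  t_end = 3, dt = 1)
  expect_equal(free_edge_speed(mv0, 1), 0)
  expect_equal(free_edge_speed(mv0, 1, "displacement"), 0)
})

test_that("equal rectangles heal into a straight midline boundary", {
  sc <- control_pair_scene()
  mv <- simulate(sc, grid = tiss_grid(10, world = sc$world), t_end = 30,
                 dt = 1 / 3)
  bc <- extract_boundary(mv[length(mv)], 1, 2)
  expect_gt(nrow(bc), 50)
  expect_true(all(abs(bc$x - 1250) <= 10))   # max deviation <= 1 pixel
})

test_that("unequal circles meet on the analytic hyperbola", {
  world <- c(3600, 3000)
  sc <- scene(list(
    tissue_seed(1, shape_circle(c(750, 1500), 500)),
    tissue_seed(2, shape_circle(c(2750, 1500), 250))), world = world)
  g <- tiss_grid(10, world = world)
  mv <- simulate(sc, grid = g, t_end = 40, dt = 1 / 3)
  f <- mv[length(mv)]

  # every boundary vertex satisfies d1 - d2 = R1 - R2 within 1.5 * spacing
  bc <- extract_boundary(f, 1, 2)
  d1 <- sqrt((bc$x - 750)^2 + (bc$y - 1500)^2)
  d2 <- sqrt((bc$x - 2750)^2 + (bc$y - 1500)^2)
  expect_true(all(abs(d1 - d2 - 250) <= 1.5 * 10))

  # first contact: gap of 1250 um closes at 2 v_n, at the point (1875, 1500)
  touched <- vapply(seq_len(length(mv)), function(i)
    nrow(extract_boundary(mv[i], 1, 2)) > 0, logical(1))
  tc <- which(touched)[1]
  expect_lt(abs(mv$times[tc] - 625 / 29.5), 0.5)
  bc0 <- extract_boundary(mv[tc], 1, 2)
  expect_lt(abs(mean(bc0$x) - (750 + 500 + 625)), 10)
  expect_lt(abs(mean(bc0$y) - 1500), 10)
})

test_that("pinning and monotone occupancy hold over whole movies", {
  set.seed(11)
  sc <- random_convex_scene(3, world = c(1600, 1600))
  mv <- simulate(sc, grid = tiss_grid(10, world = c(1600, 1600)),
                 t_end = 40, dt = 1 / 3)
  prev <- mv[1]$labels
  occ_prev <- sum(prev > 0)
  for (i in 2:length(mv)) {
    cur <- mv[i]$labels
    claimed <- prev != 0L
    expect_true(all(cur[claimed] == prev[claimed]))  # pinning
    occ <- sum(cur > 0)
    expect_gte(occ, occ_prev)                        # monotone occupancy
    prev <- cur; occ_prev <- occ
  }
  # all speeds > 0 and bounded world: free space is exhausted
  expect_equal(sum(mv[length(mv)]$labels == 0), 0)
})

test_that("simulation matches the arrival-time oracle on random convex scenes", {
  set.seed(23)
  for (rep in 1:5) {
    sc <- random_convex_scene(sample(2:3, 1), world = c(2200, 2200))
    g <- tiss_grid(10, world = c(2200, 2200))
    mv <- simulate(sc, grid = g, t_end = 45, dt = 1 / 3)
    f <- mv[length(mv)]$labels
    o <- arrival_partition(sc, g)$field$labels
    claimed <- f != 0L
    dis <- claimed & (f != o)
    expect_lt(sum(dis) / sum(claimed), 0.005)
    if (any(dis)) {
      # disagreeing pixels all lie within one pixel of an oracle boundary
      ny <- nrow(o); nx <- ncol(o)
      near_bnd <- matrix(FALSE, ny, nx)
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        src <- o[pmin(pmax(row(o) + di, 1), ny) +
                   (pmin(pmax(col(o) + dj, 1), nx) - 1) * ny]
        near_bnd <- near_bnd | (src != o)
      }
      expect_true(all(near_bnd[dis]))
    }
  }
})

test_that("mirror-symmetric scenes tessellate symmetrically", {
  sc <- control_pair_scene(world = c(2000, 1200), width = 600, gap = 400)
  g <- tiss_grid(10, world = c(2000, 1200))
  f <- simulate(sc, grid = g, t_end = 25, dt = 1 / 3)[76]$labels
  mirrored <- f[, ncol(f):1]
  swapped <- mirrored
  swapped[mirrored == 1L] <- 2L
  swapped[mirrored == 2L] <- 1L
  # disagreements only along the (tie-broken) midline: at most one column
  expect_lt(mean(f != swapped), ncol(f)^-1 + 1e-9)
})

test_that("boundary position is stable under grid refinement", {
  world <- c(2000, 1200)
  sc <- scene(list(
    tissue_seed(1, shape_circle(c(500, 600), 300)),
    tissue_seed(2, shape_circle(c(1500, 600), 200))), world = world)
  bx <- vapply(c(20, 10), function(sp) {
    mv <- simulate(sc, grid = tiss_grid(sp, world = world), t_end = 25,
                   dt = 1 / 3)
    bc <- extract_boundary(mv[length(mv)], 1, 2)
    mean(bc$x[abs(bc$y - 600) < 150])
  }, numeric(1))
  expect_lt(abs(bx[2] - bx[1]), 20)  # halving the spacing moves it < 1 coarse px
})

test_that("the arrival oracle reproduces analytic boundary conics", {
  # equal circles -> perpendicular bisector
  world <- c(2000, 1400)
  sc <- scene(list(
    tissue_seed(1, shape_circle(c(600, 700), 250)),
    tissue_seed(2, shape_circle(c(1400, 700), 250))), world = world)
  ap <- arrival_partition(sc, tiss_grid(10, world = world))
  bc <- extract_boundary(ap$field, 1, 2)
  expect_true(all(abs(bc$x - 1000) <= 10))

  # circle vs strip edge -> parabola-like conic d_circle - R = d_line
  sc2 <- scene(list(
    tissue_seed(1, shape_rectangle(c(100, 700), 200, 1400)),
    tissue_seed(2, shape_circle(c(1400, 700), 300))), world = world)
  ap2 <- arrival_partition(sc2, tiss_grid(10, world = world))
  bc2 <- extract_boundary(ap2$field, 1, 2)
  dc <- sqrt((bc2$x - 1400)^2 + (bc2$y - 700)^2) - 300
  dl <- bc2$x - 200
  expect_true(all(abs(dc - dl) <= 15))

  # non-convex seeds trigger the validity warning
  mask <- matrix(0L, 10, 10); mask[1:10, 1:2] <- 1L; mask[1:2, 1:10] <- 1L
  scL <- scene(list(tissue_seed(1, shape_mask(mask, spacing = 20))),
               world = c(400, 400))
  expect_warning(arrival_partition(scL, tiss_grid(10, world = c(400, 400))),
                 "non-convex")
})

test_that("a 6x faster tissue engulfs a slow circular tissue", {
  # strip vs circle at the homotypic speed and a 6x slower one
  world <- c(1800, 1800)
  sc <- scene(list(
    tissue_seed(1, shape_rectangle(c(200, 900), 300, 1800), speed = 29.5),
    tissue_seed(2, shape_circle(c(1150, 900), 150), speed = 29.5 / 6)),
    world = world)
  g <- tiss_grid(10, world = world)
  mv <- simulate(sc, grid = g, t_end = 50, dt = 1 / 3)
  enclosed <- vapply(seq_len(length(mv)), function(i)
    length(tissellate:::free_front_cells(mv[i]$labels, 2)) == 0, logical(1))
  expect_true(any(enclosed))             # the fast tissue fully surrounds it
  first <- which(enclosed)[1]
  a2 <- vapply(seq_len(length(mv)), function(i) label_area(mv[i], 2),
               numeric(1))
  expect_true(all(diff(a2[first:length(a2)]) == 0))  # area stops growing
  # the slow tissue's region stays bounded, in qualitative agreement with the
  # arrival-time oracle's additively weighted partition
  ap <- arrival_partition(sc, g)
  expect_lt(label_area(mv[length(mv)], 2), 1.3 * sum(ap$field$labels == 2) * 100)
})
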