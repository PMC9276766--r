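# shared fixture builders (everything is generated in code; no binary data)

make_curve <- function(x, y) {
  structure(data.frame(x = x, y = y),
            class = c("boundary_curve", "data.frame"))
}

# two equal rectangles with a 500 um gap, the control collision geometry
control_pair_scene <- function(world = c(2500, 2000), width = 1000,
                               gap = 500, speed = 29.5) {
  xc1 <- (world[1] - gap) / 2 - width / 2
  xc2 <- (world[1] + gap) / 2 + width / 2
  scene(list(
    tissue_seed(1, shape_rectangle(c(xc1, world[2] / 2), width, world[2])),
    tissue_seed(2, shape_rectangle(c(xc2, world[2] / 2), width, world[2]))),
    world = world, default_speed = speed)
}

# random non-overlapping convex seeds (circles / axis-aligned rectangles)
random_convex_scene <- function(n_seeds = 2, world = c(2200, 2200),
                                speed = 29.5) {
  repeat {
    tissues <- lapply(seq_len(n_seeds), function(k) {
      center <- stats::runif(2, 350, world - 350)
      if (stats::runif(1) < 0.5)
        tissue_seed(k, shape_circle(center, stats::runif(1, 120, 280)))
      else
        tissue_seed(k, shape_rectangle(center, stats::runif(1, 200, 500),
                                       stats::runif(1, 200, 500),
                                       angle = stats::runif(1, 0, 90)))
    })
    sc <- try(scene(tissues, world = world, default_speed = speed),
              silent = TRUE)
    if (!inherits(sc, "try-error")) return(sc)
  }
}

yaml_two_rect <- '
world: {width: 4000, height: 3000}
tissues:
  - id: 1
    shape: {kind: rectangle, center: [1000, 1500], width: 1000, height: 1000}
  - id: 2
    shape: {kind: rectangle, center: [2500, 1500], width: 1000, height: 1000}
'
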