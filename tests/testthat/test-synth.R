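test_that("electrode grids have row-major geometry at the given pitch", {
  g <- make_grid(2, 2, 17.5)
  expect_equal(unname(g),
               rbind(c(0, 0), c(17.5, 0), c(0, 17.5), c(17.5, 17.5)))
  expect_equal(nrow(make_grid(100, 100)), 10000L)
  for (p in c(17.5, 35, 70, 140)) {
    gp <- unname(make_grid(3, 3, p))
    expect_equal(gp[2L, 1L] - gp[1L, 1L], p)
    expect_equal(gp[4L, 2L] - gp[1L, 2L], p)
  }
})

test_that("arbor generation is seed-deterministic with working presets", {
  a1 <- generate_arbor(arbor_params(), seed = 3)
  a2 <- generate_arbor(arbor_params(), seed = 3)
  expect_identical(a1, a2)
  a3 <- generate_arbor(arbor_params(), seed = 4)
  expect_false(identical(a1$branches, a3$branches))

  s <- generate_arbor(arbor_params(preset = "straight"), seed = 0)
  expect_length(s$branches, 1L)
  # straight policy: all vertices on one line through the soma
  xy <- s$branches[[1L]]$xy
  expect_true(all(abs(xy[, 2L] - xy[1L, 2L]) < 1e-9))

  y <- generate_arbor(arbor_params(preset = "Y"), seed = 0)
  expect_length(y$branches, 2L)
  # daughter 2 starts exactly at a vertex of branch 1 (the bifurcation)
  bif <- y$branches[[2L]]$xy[1L, ]
  d <- sqrt((y$branches[[1L]]$xy[, 1L] - bif[1L])^2 +
            (y$branches[[1L]]$xy[, 2L] - bif[2L])^2)
  expect_lt(min(d), 1e-9)
  # daughter onset equals trunk onset plus trunk travel time
  trunk_arc <- sqrt(sum((bif - y$soma)^2))
  expect_equal(y$branches[[2L]]$onset,
               y$branches[[1L]]$onset + trunk_arc / y$branches[[1L]]$velocity,
               tolerance = 1e-9)
})

test_that("rendered peak times reproduce the ground-truth latency map", {
  sim <- suppressWarnings(simulate_footprint(arbor_params(branch_count = 2), seed = 6,
                            rows = 32, cols = 32))
  pt <- peak_time(sim$template)
  amp <- peak_to_peak(sim$template)
  rp <- render_params()
  # on channels where the axonal signal clearly dominates the soma's,
  # the measured peak equals the ground-truth latency to sample precision
  strong <- which(sim$latency_map$amplitude > 20 &
                  sim$latency_map$amplitude >
                    3 * rp$soma_peak_uv * rp$plane_offset^2 /
                    ((sim$locations[, 1] - sim$arbor$soma[1])^2 +
                     (sim$locations[, 2] - sim$arbor$soma[2])^2 +
                     rp$plane_offset^2))
  expected <- rp$soma_peak_ms + sim$latency_map$latency[strong]
  expect_lt(max(abs(pt[strong] - expected)), 1000 / rp$fs + 1e-9)
  expect_gt(length(strong), 20L)
})

test_that("amplitude follows the stated lateral decay law", {
  # single straight branch along y = 0; electrodes at known lateral offsets
  a <- structure(list(branches = list(list(xy = rbind(c(-100, 0), c(300, 0)),
                                           velocity = 300, onset = 0.3)),
                      soma = c(-300, 0), params = NULL, seed = 0),
                 class = "axon_arbor")
  loc <- rbind(c(100, 0), c(100, 10), c(100, 30))
  rp <- render_params(noise_uv = 0)
  suppressWarnings(rt <- render_template(a, loc, rp))
  amp <- rt$latency_map$amplitude
  h2 <- rp$plane_offset^2
  expect_equal(amp[2L] / amp[1L], h2 / (10^2 + h2), tolerance = 1e-6)
  expect_equal(amp[3L] / amp[1L], h2 / (30^2 + h2), tolerance = 1e-6)
  # latency equals onset + arc/velocity at the foot point
  expect_equal(rt$latency_map$latency[1L], 0.3 + 200 / 300,
               tolerance = 1e-2)
})

test_that("noise injection is seed-stable and template-shaped", {
  sim1 <- suppressWarnings(simulate_footprint(arbor_params(branch_count = 1), seed = 8,
                             rows = 16, cols = 16,
                             render = render_params(noise_uv = 5)))
  sim2 <- suppressWarnings(simulate_footprint(arbor_params(branch_count = 1), seed = 8,
                             rows = 16, cols = 16,
                             render = render_params(noise_uv = 5)))
  expect_identical(sim1$template$voltages, sim2$template$voltages)
})

test_that("ground truth round-trips through SWC plus sidecar", {
  for (preset in c("radial", "Y")) {
    arb <- generate_arbor(arbor_params(preset = preset), seed = 1,
                          soma = c(500, 500))
    tdir <- withr::local_tempdir()
    sp <- file.path(tdir, "gt.swc"); jp <- file.path(tdir, "gt.json")
    write_ground_truth(arb, sp, jp)
    back <- read_ground_truth(sp, jp)
    expect_length(back$branches, length(arb$branches))
    for (i in seq_along(arb$branches)) {
      expect_equal(back$branches[[i]]$xy, arb$branches[[i]]$xy,
                   tolerance = 1e-6)
      expect_equal(back$branches[[i]]$velocity, arb$branches[[i]]$velocity)
      expect_equal(back$branches[[i]]$onset, arb$branches[[i]]$onset)
    }
    # SWC parent pointers encode a single tree rooted at the soma
    swc <- read_swc(sp)
    expect_equal(sum(swc$parent == -1L), 1L)
    expect_true(all(swc$parent[swc$parent != -1L] %in% swc$id))
    expect_true(all(swc$id == seq_len(nrow(swc))))
  }
})
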