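test_that("starting nodes are the h_init local maxima", {
  f <- data.frame(amplitude = c(200, 10, 20, 30), peak_time = c(0, 2, 1.9, 1),
                  kurtosis = 1, peak_std = 0.1)
  loc <- rbind(c(0, 0), c(300, 0), c(350, 0), c(150, 0))
  g <- build_axon_graph(all_selected(f), f, loc,
                        axon_tracking_params(max_edge_distance = 200,
                                             init_channel_distance = 200))
  starts <- find_starting_nodes(g, loc, local_max_radius = 100)
  # node 2 (highest h_init) beats node 3 within 100 um; node 4 is a local
  # max in its own neighborhood
  expect_true(2L %in% starts)
  expect_false(3L %in% starts)

  # brute-force local-maximum scan on random fields
  for (seed in 1:4) {
    inst <- random_instance(35, seed)
    g <- build_axon_graph(all_selected(inst$features), inst$features,
                          inst$locations)
    starts <- find_starting_nodes(g, inst$locations, 100)
    h <- g$h_init
    loc <- inst$locations
    rank_of <- match(g$nodes, g$order)
    brute <- c()
    for (k in seq_along(g$nodes)) {
      d <- sqrt((loc[g$nodes, 1] - loc[g$nodes[k], 1])^2 +
                (loc[g$nodes, 2] - loc[g$nodes[k], 2])^2)
      nb <- setdiff(which(d <= 100), k)
      ok <- TRUE
      for (j in nb) {
        if (h[j] > h[k] || (h[j] == h[k] && rank_of[j] < rank_of[k]))
          ok <- FALSE
      }
      if (ok) brute <- c(brute, g$nodes[k])
    }
    expect_setequal(starts, brute)
  }
})

test_that("shortest path to init minimizes the additive edge cost", {
  # diamond: start 4 -> {2 cheap, 3 expensive} -> 1 (init)
  f <- data.frame(amplitude = c(100, 90, 10, 50),
                  peak_time = c(0.2, 0.6, 0.6, 1),
                  kurtosis = 1, peak_std = 0.1)
  loc <- rbind(c(0, 0), c(60, 40), c(60, -40), c(100, 0))
  g <- build_axon_graph(all_selected(f), f, loc)
  p <- astar_to_init(g, 4L)
  expect_equal(p, c(4L, 2L, 1L))

  # linear chain (distal channel out of range of init) is returned whole
  fc <- data.frame(amplitude = c(100, 50, 40), peak_time = c(0, 0.5, 1),
                   kurtosis = 1, peak_std = 0.1)
  locc <- rbind(c(0, 0), c(80, 0), c(160, 0))
  gc_ <- build_axon_graph(all_selected(fc), fc, locc)
  expect_equal(astar_to_init(gc_, 3L), c(3L, 2L, 1L))
})

test_that("search cost equals exhaustive enumeration on random DAGs", {
  for (seed in 1:20) {
    inst <- random_instance(12, seed, span = 150)
    g <- build_axon_graph(all_selected(inst$features), inst$features,
                          inst$locations)
    init <- g$init_channel
    for (s in setdiff(g$nodes, init)) {
      p <- astar_to_init(g, s)
      brute <- oracle_min_path_cost(g$edges, s, init)
      if (is.null(p)) {
        expect_identical(brute, Inf)
      } else {
        expect_equal(path_cost(g$edges, p), brute, tolerance = 1e-10)
      }
    }
  }
})

test_that("trimming against neighbor sets records the branching point", {
  f <- data.frame(amplitude = 100, peak_time = seq(0, 1.8, by = 0.2),
                  kurtosis = 1, peak_std = 0.1)
  loc <- cbind(0:9 * 30, 0)
  first <- 1:5                       # proximal -> distal along x
  nset <- axontrace:::channels_within(first, 1:10, loc, 100)
  # new path: channels 10..6 reversed share 6,7 with the neighbor set
  ded <- deduplicate_and_branch(c(10L, 9L, 8L, 7L, 6L), list(first),
                                list(nset), f, loc)
  expect_equal(sort(ded$channels), 9:10)
  expect_equal(ded$branch_point$path, 1L)
  expect_equal(ded$branch_point$channel, 5L)  # closest node of path 1

  # first path ever is untouched
  d0 <- deduplicate_and_branch(c(3L, 2L, 1L), list(), list(), f, loc)
  expect_equal(d0$channels, c(3L, 2L, 1L))
  expect_null(d0$branch_point)

  # fully absorbed path is discarded
  dfull <- deduplicate_and_branch(c(4L, 3L), list(first), list(nset), f, loc)
  expect_length(dfull$channels, 0L)
})

test_that("stub pruning and chain merging follow the point thresholds", {
  bp <- function(ch) list(channel = ch, path = 1L)
  # 2 channels past the branching point -> pruned
  res <- prune_and_merge(list(1:6, c(6L, 20L, 21L)), list(NULL, bp(6L)), 3L)
  expect_length(res$paths, 1L)
  # exactly 3 past the branching point -> kept (bp mid-path: no merge)
  res2 <- prune_and_merge(list(1:6, c(5L, 20L, 21L, 22L)),
                          list(NULL, bp(5L)), 3L)
  expect_length(res2$paths, 2L)
  # shared branching point at the junction of last/first channel -> merged
  res3 <- prune_and_merge(list(1:6, c(6L, 7L, 8L, 9L)), list(NULL, bp(6L)),
                          3L)
  expect_length(res3$paths, 1L)
  expect_equal(res3$paths[[1L]], 1:9)
})

test_that("raw-branch acceptance enforces both thresholds", {
  loc <- cbind(0:9 * 30, 0)
  expect_true(accept_raw_branch(1:6, loc, 100, 5))    # 150 um, 6 points
  loc80 <- cbind(seq(0, 80, length.out = 6), 0)
  expect_false(accept_raw_branch(1:6, loc80, 100, 5)) # too short
  loc200 <- cbind(c(0, 70, 140, 200), 0)
  expect_false(accept_raw_branch(1:4, loc200, 100, 5))# too few points
})

test_that("a Y-shaped arbor yields one branching point at the bifurcation", {
  sim <- suppressWarnings(simulate_footprint(arbor_params(preset = "Y"), seed = 0))
  tr <- track_axons(sim$template, sim$locations,
                    params = axon_tracking_params(max_edge_distance = 35))
  bps <- Filter(Negate(is.null), tr$branch_points)
  expect_length(bps, 1L)
  bif <- sim$arbor$branches[[2L]]$xy[1L, ]
  pos <- sim$locations[bps[[1L]]$channel, ]
  expect_lt(sqrt(sum((pos - bif)^2)), 17.5)
  expect_length(tr$branches, 2L)
})

test_that("branch reconstruction is deterministic", {
  sim <- suppressWarnings(simulate_footprint(arbor_params(), seed = 5, rows = 48, cols = 48))
  t1 <- track_axons(sim$template, sim$locations)
  t2 <- track_axons(sim$template, sim$locations)
  expect_identical(t1$raw_paths, t2$raw_paths)
  expect_identical(summary(t1), summary(t2))
})
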