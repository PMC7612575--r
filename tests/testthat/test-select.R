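features_of <- function(amplitude, peak_time = NULL, kurtosis = NULL,
                        peak_std = NULL) {
  n <- length(amplitude)
  data.frame(amplitude = amplitude,
             peak_time = peak_time %||% rep(1, n),
             kurtosis = kurtosis %||% rep(1, n),
             peak_std = peak_std %||% rep(0.1, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("amplitude filter applies relative and absolute cutoffs", {
  f <- features_of(c(100, 5, 0.5))
  expect_equal(amplitude_filter(f, 0.01, "relative"), c(TRUE, TRUE, FALSE))
  expect_equal(amplitude_filter(f, 10, "absolute"), c(TRUE, FALSE, FALSE))
  expect_equal(amplitude_filter(features_of(c(0, 0, 0))), rep(FALSE, 3))
})

test_that("kurtosis filter removes near-gaussian channels at 0.3", {
  # computed features from constructed traces, not synthetic numbers
  set.seed(3)
  spike <- c(rep(0, 120), -40, rep(0, 40)) + rnorm(161, sd = 0.5)
  noise <- rnorm(161)
  tmpl <- axon_template(rbind(spike, noise), 20000)
  f <- data.frame(kurtosis = excess_kurtosis(tmpl))
  expect_equal(kurtosis_filter(f, 0.3), c(TRUE, FALSE))
  # threshold 0 keeps every supergaussian channel
  expect_true(kurtosis_filter(f, 0)[1L])
})

test_that("peak-std filter keeps coherent neighborhoods and drops sentinels", {
  loc <- cbind((0:8) * 17.5, 0)
  coherent <- neighbor_peak_std(rep(2, 9), loc, 30)
  f1 <- data.frame(peak_std = coherent)
  expect_true(all(peak_std_filter(f1, 1)))

  spread <- neighbor_peak_std(seq(0, 40, by = 5), loc, 30)  # 5 ms steps
  expect_false(any(peak_std_filter(data.frame(peak_std = spread), 1)))

  expect_false(peak_std_filter(data.frame(peak_std = Inf), 1))
})

test_that("initial-delay filter is anchored at the largest-amplitude channel", {
  f <- features_of(c(500, 10, 10, 10), peak_time = c(1, 1.05, 1.2, 0.9))
  expect_equal(init_channel(f), 1L)
  expect_equal(init_delay_filter(f, 0.1), c(FALSE, FALSE, TRUE, FALSE))
  # delay 0 keeps all channels peaking at/after the initial channel
  expect_equal(init_delay_filter(f, 0), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("combination intersects masks and errors when nothing survives", {
  loc <- rbind(c(0, 0), c(50, 0), c(400, 0), c(60, 50))
  f <- features_of(c(500, 10, 10, 10))
  # intersection is {2, 3}, which sit 350 um apart: both isolated at 100 um,
  # leaving only the force-included initial channel -> no usable selection
  masks <- list(a = c(TRUE, TRUE, TRUE, FALSE), b = c(FALSE, TRUE, TRUE, TRUE))
  expect_error(combine_and_deisolate(masks, f, loc, isolation_radius = 100),
               "no axonal channels")
  # with a larger isolation radius both survive, plus the initial channel
  sel <- combine_and_deisolate(masks, f, loc, isolation_radius = 400)
  expect_equal(sel$init_channel, 1L)
  expect_equal(sel$selected, c(1L, 2L, 3L))
})

test_that("two close selected channels are kept, a lone distant one removed", {
  loc <- rbind(c(0, 0), c(50, 0), c(500, 0))
  f <- features_of(c(100, 90, 80))
  masks <- list(all = rep(TRUE, 3))
  sel <- combine_and_deisolate(masks, f, loc, isolation_radius = 100)
  expect_equal(sel$selected, c(1L, 2L))
  expect_true(sel$masks$isolated[3L])
})

test_that("selection equals brute-force intersection plus isolation scan", {
  set.seed(9)
  for (rep_i in 1:5) {
    n <- 30
    loc <- cbind(runif(n, 0, 300), runif(n, 0, 300))
    f <- features_of(runif(n, 1, 100))
    masks <- list(m1 = runif(n) > 0.3, m2 = runif(n) > 0.3)
    sel <- tryCatch(
      combine_and_deisolate(masks, f, loc, isolation_radius = 80),
      error = function(e) NULL)
    inter <- which(masks$m1 & masks$m2)
    keep <- c()
    for (i in inter) {
      others <- setdiff(inter, i)
      d <- sqrt((loc[others, 1] - loc[i, 1])^2 +
                (loc[others, 2] - loc[i, 2])^2)
      if (any(d <= 80)) keep <- c(keep, i)
    }
    expected <- sort(union(keep, which.max(f$amplitude)))
    if (length(expected) <= 1L) expect_null(sel) else
      expect_equal(sel$selected, expected)
  }
})

test_that("filters are monotone in their thresholds", {
  set.seed(21)
  f <- features_of(runif(50, 0, 100), kurtosis = rnorm(50, 1, 1),
                   peak_std = runif(50, 0, 2),
                   peak_time = runif(50, 0, 3))
  for (th in list(c(0.01, 0.05), c(0.05, 0.2))) {
    expect_true(all(amplitude_filter(f, th[2]) <= amplitude_filter(f, th[1])))
  }
  expect_true(all(kurtosis_filter(f, 1) <= kurtosis_filter(f, 0.3)))
  expect_true(all(peak_std_filter(f, 0.5) <= peak_std_filter(f, 1)))
  expect_true(all(init_delay_filter(f, 0.3) <= init_delay_filter(f, 0.1)))
})

test_that("full selection is permutation-equivariant", {
  sim <- suppressWarnings(simulate_footprint(arbor_params(branch_count = 2), seed = 4,
                            rows = 32, cols = 32))
  f <- channel_features(sim$template, sim$locations)
  sel <- select_channels(f, sim$locations)
  set.seed(2)
  perm <- sample(nrow(f))
  f2 <- f[perm, ]; rownames(f2) <- NULL
  sel2 <- select_channels(f2, sim$locations[perm, ])
  expect_setequal(perm[sel2$selected], sel$selected)
  expect_equal(perm[sel2$init_channel], sel$init_channel)
})
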