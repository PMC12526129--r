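test_that("chain clustering is transitive and strict at the cutoff", {
  # three collinear dimers: A-B touch, B-C touch, A-C far -> one cluster
  pos <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.0, 0, 0))
  sys <- particle_system(pos, "UA", "X", chain = c("A", "B", "C"))
  cs <- find_clusters(sys, cutoff = 0.6)
  expect_length(cs$clusters, 1)
  expect_setequal(cs$clusters[[1]], c("A", "B", "C"))
  # a pair at exactly the cutoff is NOT in contact (strict inequality)
  sys2 <- particle_system(rbind(c(0, 0, 0), c(0.6, 0, 0)), "UA", "X",
                          chain = c("A", "B"))
  expect_length(find_clusters(sys2, cutoff = 0.6)$clusters, 2)
  expect_length(find_clusters(sys2, cutoff = 0.6 + 1e-9)$clusters, 1)
})

test_that("clustering sees contacts across the periodic boundary", {
  box <- c(3, 3, 3)
  pos <- rbind(c(0.1, 1, 1), c(2.9, 1, 1))  # 0.2 nm apart through the wall
  sys <- particle_system(pos, "UA", "X", chain = c("A", "B"), box = box)
  expect_length(find_clusters(sys, cutoff = 0.6)$clusters, 1)
  sys_nopbc <- particle_system(pos, "UA", "X", chain = c("A", "B"))
  expect_length(find_clusters(sys_nopbc, cutoff = 0.6)$clusters, 2)
})

test_that("clustering matches a union-find oracle on crowded random systems", {
  for (s in 1:4) {
    sys <- random_chain_system(30, beads_per_chain = 3, seed = 400 + s)
    cs <- find_clusters(sys, cutoff = 0.6)
    oracle <- union_find_clusters(sys, cutoff = 0.6)
    expect_true(same_partition(cs$clusters, oracle))
  }
})

test_that("growing the cutoff can merge clusters but never split them", {
  sys <- random_chain_system(25, seed = 77)
  small <- find_clusters(sys, cutoff = 0.4)
  large <- find_clusters(sys, cutoff = 0.8)
  expect_gte(length(small$clusters), length(large$clusters))
  # every small-cutoff cluster sits inside exactly one large-cutoff cluster
  for (cl in small$clusters) {
    hosts <- unique(large$membership[cl])
    expect_length(hosts, 1)
  }
})

test_that("cluster results are invariant under chain relabeling", {
  sys <- random_chain_system(20, seed = 55)
  relabeled <- sys
  ids <- unique(sys$chain)
  new_ids <- setNames(sprintf("z%02d", rev(seq_along(ids))), ids)
  relabeled$chain <- unname(new_ids[sys$chain])
  a <- find_clusters(sys, cutoff = 0.6)$clusters
  b <- find_clusters(relabeled, cutoff = 0.6)$clusters
  b_mapped <- lapply(b, function(cl) names(new_ids)[match(cl, new_ids)])
  expect_true(same_partition(a, b_mapped))
})

test_that("a noiseless power law is recovered exactly by the exponent fit", {
  for (alpha in c(0.25, 0.91)) {
    gs <- fit_growth_exponent(synth_growth_series(alpha, noise_sd = 0))
    expect_lt(abs(gs$alpha - alpha), 1e-10)
  }
  flat <- fit_growth_exponent(growth_series(1:20, rep(3, 20)))
  expect_equal(flat$alpha, 0, tolerance = 1e-12)
  expect_error(growth_series(1:3, c(1, -1, 2)), "positive")
  expect_error(fit_growth_exponent(growth_series(1:3, 1:3)), "at least 5")
})

test_that("the noisy exponent estimate is unbiased across seeds and its SE is honest", {
  alphas <- vapply(1:20, function(s)
    fit_growth_exponent(synth_growth_series(0.25, noise_sd = 0.2,
                                            seed = s))$alpha, 0)
  se <- sd(alphas) / sqrt(length(alphas))
  expect_lt(abs(mean(alphas) - 0.25), 2 * se)
  # the per-fit standard error is the right order of magnitude
  one <- fit_growth_exponent(synth_growth_series(0.25, noise_sd = 0.2,
                                                 seed = 1))
  expect_gt(one$alpha_se, sd(alphas) / 3)
  expect_lt(one$alpha_se, sd(alphas) * 3)
})

test_that("fit ranges restrict the exponent regression to the requested interval", {
  # piecewise series: slope 1 up to t = 10, flat afterwards
  t <- 1:40
  n <- ifelse(t <= 10, t, 10)
  early <- fit_growth_exponent(growth_series(t, n), fit_range = c(1, 10))
  late <- fit_growth_exponent(growth_series(t, n), fit_range = c(11, 40))
  expect_equal(early$alpha, 1, tolerance = 1e-12)
  expect_equal(late$alpha, 0, tolerance = 1e-12)
})

test_that("encounter events are maximal below-threshold intervals with their minima", {
  times <- 0:380
  d <- 47.5 + 22.5 * cos(times / 20)  # spans 25-70, dips below 30 three times
  ev <- encounter_events(times, d, threshold = 30)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$min_distance >= 25 & ev$min_distance < 30))
  expect_true(all(ev$start < ev$end))
  # intervals are disjoint and ordered
  expect_true(all(diff(ev$start) > 0))
  expect_true(all(ev$end[-3] < ev$start[-1]))
  none <- encounter_events(times, d, threshold = 20)
  expect_equal(nrow(none), 0)
})

test_that("cluster centers of mass unwrap correctly across the boundary", {
  box <- c(2, 2, 2)
  # two particles straddling the x wall: COM must sit at the wall, not mid-box
  com <- cluster_com(rbind(c(0.1, 1, 1), c(1.9, 1, 1)), box = box)
  expect_equal((com[1] + 2) %% 2, 0, tolerance = 1e-12)
  expect_equal(com[2:3], c(1, 1))
  # without a box the plain mean is returned
  expect_equal(cluster_com(rbind(c(0.1, 1, 1), c(1.9, 1, 1))), c(1, 1, 1))
})

test_that("COM distance series flags encounters and fusions between tracked groups", {
  mk <- function(dx, touch = FALSE) {
    pos <- rbind(c(1, 1, 1), c(1.3, 1, 1),
                 c(1 + dx, 1, 1), c(1.3 + dx, 1, 1))
    if (touch) pos[3, ] <- c(1.3 + 0.4, 1, 1)
    particle_system(pos, "UA", "X", chain = c("A", "A", "B", "B"),
                    box = c(6, 6, 6))
  }
  frames <- list(mk(3.0), mk(2.0), mk(1.0), mk(1.0, touch = TRUE), mk(2.5))
  ser <- com_distance_series(frames, "A", "B", threshold = 1.5,
                             fuse_cutoff = 0.6)
  expect_equal(ser$distance[1], 3.0)
  expect_equal(nrow(ser$encounters), 1)
  expect_equal(ser$encounters$start, 3)
  expect_true(4 %in% ser$fusions)
  expect_false(1 %in% ser$fusions)
  expect_error(com_distance_series(frames, "A", "A"), "disjoint")
})
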