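test_that("a single unbiased window reduces WHAM to Boltzmann inversion of its histogram", {
  dw <- make_double_well()
  w <- metropolis_window(dw, center = NA, n_samples = 20000, step_sd = 0.08,
                         seed = 17, r_init = 0.4)
  prof <- wham(list(w), r_min = 0.3, r_max = 0.9, bin_width = 0.02)
  edges <- seq(0.3, 0.9, by = 0.02)
  h <- tabulate(findInterval(w$samples[w$samples >= 0.3 & w$samples < 0.9],
                             edges), nbins = length(edges) - 1)
  kT <- 0.0083144621 * 310
  ok <- prof$counts > 0
  manual <- -kT * log(h[ok])
  manual <- manual - manual[length(manual)]  # same zero-at-rmax convention
  expect_equal(prof$counts[ok], h[ok])
  expect_equal(prof$free_energy[ok], manual, tolerance = 1e-10)
})

test_that("WHAM reconstructs a known double-well potential from overlapping windows", {
  dw <- make_double_well()
  centers <- generate_window_centers(0.3, 0.9, 8)
  wins <- lapply(seq_along(centers), function(i)
    metropolis_window(dw, center = centers[i], k = 500, n_samples = 12000,
                      step_sd = 0.05, seed = 100 + i))
  prof <- wham(wins, r_min = 0.3, r_max = 0.95, bin_width = 0.01)
  ok <- prof$counts > 100
  ref <- dw(prof$r[ok])
  est <- prof$free_energy[ok]
  d <- (est - mean(est)) - (ref - mean(ref))
  expect_lt(sqrt(mean(d^2)), 0.2)
  # the self-consistent iteration actually converged
  res <- attr(prof, "residuals")
  expect_lt(res[length(res)], 1e-7)
})

test_that("WHAM refuses a window chain with a sampling gap, naming the gap", {
  pot <- function(r) 0 * r
  w1 <- metropolis_window(pot, center = 0.3, k = 5000, n_samples = 1000,
                          step_sd = 0.01, seed = 1)
  w2 <- metropolis_window(pot, center = 0.9, k = 5000, n_samples = 1000,
                          step_sd = 0.01, seed = 2)
  expect_error(wham(list(w1, w2), r_min = 0.25, r_max = 1.0, bin_width = 0.01),
               "non-overlapping.*0\\.300.*0\\.900")
})

test_that("the radial-entropy correction shifts the profile by exactly 2 kT ln r", {
  dw <- make_double_well()
  centers <- generate_window_centers(0.35, 0.85, 6)
  wins <- lapply(seq_along(centers), function(i)
    metropolis_window(dw, center = centers[i], k = 500, n_samples = 3000,
                      step_sd = 0.05, seed = 50 + i))
  p0 <- wham(wins, r_min = 0.3, r_max = 0.9, bin_width = 0.02,
             jacobian = FALSE, zero = "min-is-zero")
  p1 <- wham(wins, r_min = 0.3, r_max = 0.9, bin_width = 0.02,
             jacobian = TRUE, zero = "min-is-zero")
  ok <- p0$counts > 0
  kT <- 0.0083144621 * 310
  diff_prof <- p1$free_energy[ok] - p0$free_energy[ok] - 2 * kT * log(p0$r[ok])
  expect_lt(max(diff_prof) - min(diff_prof), 1e-9)
})

test_that("the zero conventions anchor profiles where they promise to", {
  r <- seq(0.3, 1.0, by = 0.01)
  f <- lj_energy(r, 2, 0.47)
  p_rmax <- pmf_profile(r, f, zero = "zero-at-rmax")
  expect_equal(p_rmax$free_energy[length(r)], 0)
  p_min <- pmf_profile(r, f, zero = "min-is-zero")
  expect_equal(min(p_min$free_energy), 0)
  expect_error(pmf_profile(r[-1], f), "equal length")
  expect_error(pmf_profile(rev(r), f), "strictly increasing")
})

test_that("the first-minimum locator finds the Lennard-Jones well to sub-bin accuracy", {
  eps <- 1; sig <- 0.47
  r <- seq(0.4, 1.0, by = 0.01)
  prof <- pmf_profile(r, lj_energy(r, eps, sig))
  m <- first_minimum(prof)
  expect_true(m$found)
  expect_lt(abs(m$position - 2^(1 / 6) * sig), 0.01)
  expect_lt(abs(m$depth - eps) / eps, 0.05)
})

test_that("the first of two minima is reported and monotone profiles yield the no-minimum result", {
  dw <- make_double_well(r1 = 0.4, r2 = 0.7)
  r <- seq(0.3, 0.9, by = 0.005)
  m <- first_minimum(pmf_profile(r, dw(r)))
  expect_true(m$found)
  expect_lt(abs(m$position - 0.4), 0.01)
  mono <- first_minimum(pmf_profile(r, 5 * exp(-r)))
  expect_false(mono$found)
  expect_error(first_minimum(pmf_profile(seq(0.3, 0.9, length.out = 4),
                                         rep(1, 4))),
               "at least 5")
})

test_that("smoothing suppresses spurious single-bin minima without moving a real well", {
  set.seed(31)
  r <- seq(0.35, 1.0, by = 0.01)
  f <- lj_energy(r, 2, 0.47) + rnorm(length(r), 0, 0.05)
  m <- first_minimum(pmf_profile(r, f), smoothing = 5)
  expect_true(m$found)
  expect_lt(abs(m$position - 2^(1 / 6) * 0.47), 0.03)
})

test_that("profile deviations are absolute differences of well descriptors", {
  r <- seq(0.35, 1.0, by = 0.005)
  a <- pmf_profile(r, lj_energy(r, 2.0, 0.47))
  b <- pmf_profile(r, lj_energy(r, 2.5, 0.50))
  dev <- pmf_deviation(a, b)
  expect_equal(dev$d_depth, abs(first_minimum(a)$depth - first_minimum(b)$depth))
  expect_lt(abs(dev$d_position - 2^(1 / 6) * 0.03), 0.005)
  mono <- pmf_profile(r, 5 * exp(-r))
  expect_error(pmf_deviation(mono, a), "no first minimum")
})

test_that("scalar Metropolis and 3-D Langevin umbrella routes agree on the same pair potential", {
  eps <- 2; sig <- 0.47
  true_pos <- 2^(1 / 6) * sig
  centers <- generate_window_centers(0.35, 0.95, 8)
  mc_wins <- lapply(seq_along(centers), function(i)
    metropolis_window(function(r) lj_energy(r, eps, sig), center = centers[i],
                      k = 500, n_samples = 8000, step_sd = 0.05,
                      seed = 200 + i))
  pmf_mc <- wham(mc_wins, r_min = 0.3, r_max = 1.0, bin_width = 0.01)
  tab <- pair_table(data.frame(type_i = "A", type_j = "A",
                               epsilon = eps, sigma = sig),
                    eps_cg = 1, eps_dual = 1)
  ld_wins <- lapply(seq_along(centers), function(i) {
    sys <- particle_system(rbind(c(1.5, 1.5, 1.5),
                                 c(1.5, 1.5 + centers[i], 1.5)),
                           "UA", "A", mass = 72)
    run_umbrella_window(sys, tab, 1, 2, centers[i], k = 500,
                        conditions = sim_conditions(310, 5, 0.004, 6000,
                                                    seed = 300 + i),
                        stride = 5)
  })
  # the 3-D route samples an isotropic separation vector, so it needs the
  # radial entropy correction; the scalar route must not have it
  pmf_ld <- wham(ld_wins, r_min = 0.3, r_max = 1.0, bin_width = 0.01,
                 jacobian = TRUE)
  m_mc <- first_minimum(pmf_mc, smoothing = 3)
  m_ld <- first_minimum(pmf_ld, smoothing = 3)
  expect_lt(abs(m_mc$position - true_pos), 0.02)
  expect_lt(abs(m_ld$position - true_pos), 0.02)
  expect_lt(abs(m_mc$depth - eps), 1.0)
  expect_lt(abs(m_ld$depth - eps), 1.0)
})
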