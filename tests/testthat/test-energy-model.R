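test_that("Lennard-Jones energy matches its closed form at landmark points", {
  eps <- 2.3; sig <- 0.47
  expect_equal(lj_energy(2^(1 / 6) * sig, eps, sig), -eps)
  expect_equal(lj_energy(sig, eps, sig), 0)
  expect_equal(lj_energy(2 * sig, eps, sig), -63 / 1024 * eps)
  # shifted form vanishes at the cutoff and differs by a constant elsewhere
  expect_equal(lj_energy(1.2, eps, sig, shift = TRUE), 0)
  r <- seq(0.35, 1.1, by = 0.05)
  expect_equal(lj_energy(r, eps, sig, shift = TRUE) - lj_energy(r, eps, sig),
               rep(-lj_energy(1.2, eps, sig), length(r)))
  expect_error(lj_energy(-0.1, eps, sig), "positive")
  expect_error(lj_energy(0.5, eps, -1), "sigma|non-negative")
})

test_that("reaction-field electrostatics vanishes at the cutoff and has the conducting-boundary curvature", {
  rc <- 1.2
  expect_equal(coulomb_reaction_field(rc, 1, -1, cutoff = rc), 0)
  expect_equal(coulomb_reaction_field(rc + 0.3, 1, -1, cutoff = rc), 0)
  # conducting boundary: k_rf = 1/(2 rc^3), so U(r) = f q1 q2 (1/r + r^2/(2rc^3) - 3/(2rc))
  f <- 138.935458
  r <- c(0.3, 0.6, 1.0)
  expect_equal(coulomb_reaction_field(r, 1, 1, cutoff = rc),
               f * (1 / r + r^2 / (2 * rc^3) - 3 / (2 * rc)))
  # a finite reaction-field dielectric still gives zero at the cutoff
  expect_equal(coulomb_reaction_field(rc, 2, 1, cutoff = rc, rf_dielectric = 78),
               0)
  # dielectric scales the whole energy down
  expect_equal(coulomb_reaction_field(0.5, 1, 1, dielectric = 15),
               coulomb_reaction_field(0.5, 1, 1, dielectric = 1) / 15)
})

test_that("Lorentz-Berthelot combination and the scaling layer behave as specified", {
  comb <- combine_lorentz_berthelot(4, 0.4, 9, 0.6)
  expect_equal(comb$epsilon, 6)
  expect_equal(comb$sigma, 0.5)

  tab <- random_mixed_table(eps_cg = 0.2, eps_dual = 0.8)
  expect_equal(scaling_factor(tab, "UA", "UA"), 1)
  expect_equal(scaling_factor(tab, "CG", "CG"), 0.2)
  expect_equal(scaling_factor(tab, "UA", "CG"), 0.8)
  expect_equal(scaling_factor(tab, "CG", "UA"), 0.8)

  sc <- apply_scaling(tab)
  # sigma is never rescaled; only well depths are
  expect_equal(sc$sigma, unname(tab$sigma))
  expect_equal(sc$epsilon_cg_cg, sc$epsilon_ua_ua * 0.2)
  expect_equal(sc$epsilon_ua_cg, sc$epsilon_ua_ua * 0.8)

  expect_error(pair_table(data.frame(type_i = "A", type_j = "A",
                                     epsilon = 1, sigma = 0.4), eps_cg = 3),
               "\\(0, 2\\]")
})

test_that("pair lookup is symmetric, alias-aware, and loud about unknown pairs", {
  tab <- pair_table(data.frame(type_i = c("ASN", "ASN"),
                               type_j = c("ASN", "LEU"),
                               epsilon = c(2.8, 3.1), sigma = c(0.45, 0.47)),
                    aliases = c(BB = "ASN"))
  expect_equal(lookup_pair(tab, "LEU", "ASN"), lookup_pair(tab, "ASN", "LEU"))
  # the alias borrows the aliased type's parameters everywhere
  expect_equal(lookup_pair(tab, "BB", "BB"), lookup_pair(tab, "ASN", "ASN"))
  expect_equal(lookup_pair(tab, "BB", "LEU"), lookup_pair(tab, "ASN", "LEU"))
  expect_error(lookup_pair(tab, "LEU", "TRP"), "LEU - TRP")
  expect_error(
    pair_table(data.frame(type_i = c("A", "B"), type_j = c("B", "A"),
                          epsilon = c(1, 2), sigma = c(0.4, 0.4))),
    "conflicting duplicate")
})

test_that("the three-way decomposition identity holds to machine precision on random systems", {
  tab <- random_mixed_table()
  worst <- 0
  for (s in 1:25) {
    sys <- random_mixed_system(20, seed = 1000 + s)
    dec <- energy_decomposition(sys, tab)
    err <- abs(dec$U_total - (dec$U_UA + dec$U_CG + dec$U_UA_CG)) /
      (1 + abs(dec$U_total))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-12)
})

test_that("vectorized energies equal a naive double-loop oracle", {
  tab <- random_mixed_table()
  for (s in 1:5) {
    sys <- random_mixed_system(24, seed = 2000 + s)
    dec <- energy_decomposition(sys, tab)
    ref <- brute_force_energy(sys, tab)
    expect_equal(dec$U_UA, ref$U_UA, tolerance = 1e-10)
    expect_equal(dec$U_CG, ref$U_CG, tolerance = 1e-10)
    expect_equal(dec$U_UA_CG, ref$U_UA_CG, tolerance = 1e-10)
    expect_equal(dec$U_total, ref$U_total, tolerance = 1e-10)
  }
})

test_that("minimum-image energies agree with explicit 27-image enumeration", {
  tab <- random_mixed_table()
  for (s in 1:3) {
    sys <- random_mixed_system(18, seed = 3000 + s)
    expect_equal(potential_energy(sys, tab),
                 image_oracle_energy(sys, tab), tolerance = 1e-10)
  }
})

test_that("the CG-CG energy component is exactly linear in the CG scaling factor", {
  sys <- random_mixed_system(20, seed = 7, charged = FALSE)
  u_cg_at <- function(f) {
    energy_decomposition(sys, random_mixed_table(eps_cg = f, eps_dual = 0.8))$U_CG
  }
  base <- u_cg_at(1)
  for (f in c(0.1, 0.2, 0.5, 1.5)) {
    expect_equal(u_cg_at(f), f * base, tolerance = 1e-12)
  }
  # and the other two components are untouched by it
  d1 <- energy_decomposition(sys, random_mixed_table(eps_cg = 0.2))
  d2 <- energy_decomposition(sys, random_mixed_table(eps_cg = 1.7))
  expect_equal(d1$U_UA, d2$U_UA)
  expect_equal(d1$U_UA_CG, d2$U_UA_CG)
})

test_that("energies are invariant under rigid translation and particle relabeling", {
  tab <- random_mixed_table()
  sys <- random_mixed_system(20, seed = 11)
  u0 <- potential_energy(sys, tab)
  shifted <- sys
  shifted$positions <- sweep(sys$positions, 2, c(0.73, -1.19, 0.31), `+`)
  expect_equal(potential_energy(shifted, tab), u0, tolerance = 1e-12)

  perm <- sample(n_particles(sys))
  reord <- particle_system(sys$positions[perm, ], sys$resolution[perm],
                           sys$type[perm], charge = sys$charge[perm],
                           mass = sys$mass[perm], box = sys$box)
  expect_equal(potential_energy(reord, tab), u0, tolerance = 1e-12)
})

test_that("excluded pairs contribute nothing to energies or forces", {
  tab <- random_mixed_table()
  pos <- rbind(c(0.5, 0.5, 0.5), c(0.9, 0.5, 0.5), c(0.5, 1.1, 0.5))
  base <- particle_system(pos, "UA", c("LEU", "LEU", "SER"), mass = 72)
  excl <- particle_system(pos, "UA", c("LEU", "LEU", "SER"), mass = 72,
                          exclusions = cbind(1L, 2L))
  p12 <- lookup_pair(tab, "LEU", "LEU")
  u12 <- lj_energy(0.4, p12$epsilon, p12$sigma, shift = TRUE)
  expect_equal(potential_energy(base, tab) - potential_energy(excl, tab), u12)
})

test_that("analytic forces match numerical gradients and obey Newton's third law", {
  tab <- random_mixed_table()
  sys <- random_mixed_system(12, seed = 21)
  f <- compute_forces(sys, tab)
  expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-9)
  h <- 1e-6
  for (i in c(1, 5, 12)) {
    for (k in 1:3) {
      sp <- sys; sp$positions[i, k] <- sp$positions[i, k] + h
      sm <- sys; sm$positions[i, k] <- sm$positions[i, k] - h
      num <- -(potential_energy(sp, tab) - potential_energy(sm, tab)) / (2 * h)
      expect_equal(f[i, k], num, tolerance = 1e-4)
    }
  }
})
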