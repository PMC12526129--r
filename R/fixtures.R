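# Deterministic generators for every desk-scale test input: analog dimer
# boxes, toy polymers, ideal beta-sheets of known registry, a micelle-forming
# amphiphile mixture, and synthetic growth series.

#' The twelve representative side-chain analogs
#'
#' One representative per MARTINI side-chain bead chemistry class (several
#' amino acids share a bead type, e.g. Leu/Ile or Ser/Thr), so fitting these
#' twelve covers the full cross-interaction matrix.
#' @return Character vector of 12 three-letter analog labels.
#' @export
default_analogs <- function() {
  c("LEU", "VAL", "CYS", "SER", "ASN", "GLN",
    "GLU", "ARG", "LYS", "HIS", "PHE", "TRP")
}

#' A plausible toy pair table over the default analogs
#'
#' Per-analog base well depths and sizes (loosely ranked by hydrophobicity
#' and bead size) combined with the Lorentz-Berthelot rule into a full
#' symmetric table. These are stand-in values for exercising the machinery,
#' not fitted parameters.
#'
#' @param analogs analog labels (default [default_analogs()]).
#' @param ... passed to [pair_table()] (scaling factors, cutoff, ...).
#' @return A `pair_table` covering every analog pair.
#' @export
default_analog_table <- function(analogs = default_analogs(), ...) {
  base_eps <- c(LEU = 4.5, VAL = 4.0, CYS = 3.5, SER = 2.5, ASN = 2.8,
                GLN = 3.0, GLU = 2.6, ARG = 2.4, LYS = 2.2, HIS = 3.2,
                PHE = 4.8, TRP = 5.0)
  base_sig <- c(LEU = 0.49, VAL = 0.46, CYS = 0.45, SER = 0.42, ASN = 0.45,
                GLN = 0.47, GLU = 0.47, ARG = 0.52, LYS = 0.50, HIS = 0.48,
                PHE = 0.52, TRP = 0.55)
  miss <- setdiff(analogs, names(base_eps))
  if (length(miss) > 0) {
    base_eps[miss] <- 3.0
    base_sig[miss] <- 0.47
  }
  grid <- expand.grid(i = analogs, j = analogs, stringsAsFactors = FALSE)
  grid <- grid[grid$i <= grid$j, ]
  comb <- combine_lorentz_berthelot(base_eps[grid$i], base_sig[grid$i],
                                    base_eps[grid$j], base_sig[grid$j])
  pair_table(data.frame(type_i = grid$i, type_j = grid$j,
                        epsilon = unname(comb$epsilon),
                        sigma = unname(comb$sigma)), ...)
}

#' Enumerate all ordered analog dimer systems
#'
#' One two-particle dimer box per ORDERED analog pair: the first member is
#' tagged UA and the second CG, so a heterodimer appears twice with swapped
#' resolutions (the two cross-resolution variants are distinct systems). The
#' default twelve analogs give 12 x 12 = 144 systems.
#'
#' @param analogs analog labels (no duplicates).
#' @param separation initial separation in nm.
#' @param box box edge lengths in nm (default `c(3, 4, 3)`).
#' @return Named list of `particle_system` dimers (`"UA_X|CG_Y"` keys).
#' @export
enumerate_analog_pairs <- function(analogs = default_analogs(),
                                   separation = 0.5, box = c(3, 4, 3)) {
  if (length(analogs) == 0L) stop("analog list must be non-empty")
  if (anyDuplicated(analogs)) stop("duplicate analog labels")
  out <- list()
  for (a in analogs) for (b in analogs) {
    sys <- particle_system(
      positions = rbind(c(box[1] / 2, box[2] / 2 - separation / 2, box[3] / 2),
                        c(box[1] / 2, box[2] / 2 + separation / 2, box[3] / 2)),
      resolution = c("UA", "CG"), type = c(a, b),
      mass = c(72, 72), chain = c("A", "B"), box = box)
    out[[paste0("UA_", a, "|CG_", b)]] <- sys
  }
  out
}

#' Build an ideal beta-sheet of known registry
#'
#' Extended strands of the five-residue repeat L1-V2-F3-F4-A5 laid out at
#' canonical geometry: 0.35 nm C-alpha spacing along the strand and 0.48 nm
#' between strands. For `registry = "parallel"` all strands run the same way
#' and, at `register_shift = 0`, core residues pair identically (1-1 ... 4-4).
#' For `"antiparallel"` alternate strands are reversed and offset so the core
#' pairing is exactly reversed (1-4, 2-3, 3-2, 4-1). A nonzero
#' `register_shift` slides every other strand by that many residue spacings,
#' breaking the in-register pairing.
#'
#' @param n_strands number of strands (>= 2).
#' @param registry `"parallel"` or `"antiparallel"`.
#' @param register_shift integer residue shift (|shift| < strand length).
#' @return A `particle_system` with one C-alpha site per residue, chains
#'   `"S1"`, `"S2"`, ..., residues labeled L/V/F/F/A with resid 1-5.
#' @export
build_beta_sheet <- function(n_strands = 2L, registry = c("parallel", "antiparallel"),
                             register_shift = 0L) {
  registry <- match.arg(registry)
  if (n_strands < 2L) stop("need at least 2 strands")
  resnames <- c("LEU", "VAL", "PHE", "PHE", "ALA")
  n_res <- length(resnames)
  if (abs(register_shift) >= n_res)
    stop("|register_shift| must be smaller than the strand length")
  dx <- 0.35; dy <- 0.48
  pos <- NULL; chain <- character(0); resid <- integer(0); resname <- character(0)
  for (s in seq_len(n_strands) - 1L) {
    reversed <- registry == "antiparallel" && s %% 2L == 1L
    xs <- if (reversed) (4L - seq_len(n_res)) * dx else (seq_len(n_res) - 1L) * dx
    if (s %% 2L == 1L) xs <- xs + register_shift * dx
    pos <- rbind(pos, cbind(xs, s * dy, 0))
    chain <- c(chain, rep(sprintf("S%d", s + 1L), n_res))
    resid <- c(resid, seq_len(n_res))
    resname <- c(resname, resnames)
  }
  particle_system(pos, resolution = "UA", type = "CA", mass = 12,
                  chain = chain, resid = resid, resname = resname)
}

#' Build a toy amphiphile mixture
#'
#' `n` two-bead amphiphiles — a sticky hydrophobic tail bead (UA tag, strong
#' Lennard-Jones self-attraction) bonded to a charged head bead (CG tag,
#' weak self-attraction, charge `head_charge`) — placed without overlap in a
#' non-periodic region. Under the toy dynamics the tails condense into a
#' core while the charged heads stay peripheral, the minimal core-corona
#' architecture of a peptide micelle with a hydrophobic aggregation core and
#' a polycationic crown.
#'
#' @param n_amphiphiles number of two-bead chains (>= 2).
#' @param head_charge head bead charge in e (default +1; electrostatics are
#'   screened with a relative dielectric of 15, the usual CG convention).
#' @param tail_epsilon tail-tail well depth in kJ/mol (default 10, a few kT,
#'   so tails condense on the toy time scale).
#' @param head_epsilon head-head well depth (default 0.5).
#' @param sigma bead diameter in nm.
#' @param bond_length tail-head bond length in nm.
#' @param region placement region half-width in nm.
#' @param seed RNG seed (placement is deterministic per seed).
#' @param max_tries placement retries before giving up.
#' @return List with the `particle_system` (`system`), its `pair_table`
#'   (`table`), the bond list (`bonds`, two-column index matrix), and bead
#'   index vectors `tails`, `heads`.
#' @export
build_micelle_toy <- function(n_amphiphiles = 12L, head_charge = 1,
                              tail_epsilon = 10, head_epsilon = 0.5,
                              sigma = 0.47, bond_length = 0.5,
                              region = 1.2, seed = 1L, max_tries = 2000L) {
  if (n_amphiphiles < 2L) stop("need at least 2 amphiphiles")
  set.seed(seed)
  pos <- matrix(NA_real_, 2L * n_amphiphiles, 3L)
  placed <- 0L; tries <- 0L
  while (placed < n_amphiphiles) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place amphiphiles without overlap; lower the density")
    mid <- stats::runif(3, -region, region)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    # symmetric about the midpoint so neither bead class starts biased outward
    tail <- mid - dir * bond_length / 2
    head <- mid + dir * bond_length / 2
    cand <- rbind(tail, head)
    if (placed > 0L) {
      prev <- pos[seq_len(2L * placed), , drop = FALSE]
      dmin <- sqrt(min(outer_pair_dist2(cand, prev)))
      if (dmin < 0.9 * sigma) next
    }
    pos[2L * placed + 1:2, ] <- cand
    placed <- placed + 1L
  }
  n <- 2L * n_amphiphiles
  tails <- seq(1L, n, by = 2L); heads <- seq(2L, n, by = 2L)
  type <- rep(c("TAIL", "HEAD"), n_amphiphiles)
  resolution <- rep(c("UA", "CG"), n_amphiphiles)
  charge <- rep(c(0, head_charge), n_amphiphiles)
  chain <- rep(sprintf("M%d", seq_len(n_amphiphiles)), each = 2L)
  bonds <- cbind(tails, heads)
  sys <- particle_system(pos, resolution = resolution, type = type,
                         charge = charge, mass = 72, chain = chain,
                         resid = rep(1L, n), exclusions = bonds)
  cross <- combine_lorentz_berthelot(tail_epsilon, sigma, head_epsilon, sigma)
  tab <- pair_table(data.frame(
    type_i = c("TAIL", "HEAD", "TAIL"),
    type_j = c("TAIL", "HEAD", "HEAD"),
    epsilon = c(tail_epsilon, head_epsilon, cross$epsilon),
    sigma = c(sigma, sigma, cross$sigma)),
    eps_cg = 1, eps_dual = 1, cutoff = 1.2,
    dielectric = 15)  # screened CG electrostatics, MARTINI convention
  list(system = sys, table = tab, bonds = bonds, tails = tails, heads = heads)
}

#' Relax a toy amphiphile mixture and score its core-corona ordering
#'
#' Runs Langevin dynamics on a [build_micelle_toy()] system (harmonic
#' tail-head bonds plus the amphiphile pair table) and returns the
#' [radial_ordering()] statistic averaged over the final third of the
#' trajectory: positive values mean the charged heads sit farther from the
#' assembly center than the sticky tails.
#'
#' @param n_amphiphiles number of chains.
#' @param head_charge,tail_epsilon,head_epsilon passed to
#'   [build_micelle_toy()].
#' @param n_steps Langevin steps.
#' @param seed RNG seed (placement and dynamics).
#' @param temperature,friction,timestep dynamics settings.
#' @return List with `ordering` (mean statistic, nm), `final` (the relaxed
#'   `particle_system`), and the builder output (`tails`, `heads`).
#' @export
relax_micelle_toy <- function(n_amphiphiles = 10L, head_charge = 1,
                              tail_epsilon = 10, head_epsilon = 0.5,
                              n_steps = 8000L, seed = 1L, temperature = 310,
                              friction = 2, timestep = 0.004) {
  mic <- build_micelle_toy(n_amphiphiles, head_charge = head_charge,
                           tail_epsilon = tail_epsilon,
                           head_epsilon = head_epsilon, seed = seed)
  bf <- harmonic_bond_force(mic$bonds, b0 = 0.5, k = 2000)
  cond <- sim_conditions(temperature = temperature, friction = friction,
                         timestep = timestep, n_steps = n_steps, seed = seed)
  n_chain <- n_amphiphiles
  chains <- sprintf("M%d", seq_len(n_chain))
  # per-frame ordering inside the largest tail cluster (global COM is
  # meaningless while several small clusters coexist)
  cluster_ordering <- function(x) {
    tails_pos <- x[mic$tails, , drop = FALSE]
    d2 <- outer_pair_dist2(tails_pos, tails_pos)
    g <- igraph::graph_from_adjacency_matrix(d2 < 0.7^2, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    big <- which(comp$membership == which.max(comp$csize))
    if (length(big) < 3L) return(NA_real_)
    sel_t <- mic$tails[big]; sel_h <- mic$heads[big]
    com <- center_of_mass(x[c(sel_t, sel_h), , drop = FALSE])
    mean(sqrt(rowSums(sweep(x[sel_h, , drop = FALSE], 2, com)^2))) -
      mean(sqrt(rowSums(sweep(x[sel_t, , drop = FALSE], 2, com)^2)))
  }
  out <- run_langevin(mic$system, mic$table, cond,
                      observe = cluster_ordering,
                      stride = 40L, extra_force = bf)
  ser <- as.numeric(out$series)
  tail_part <- ser[seq.int(ceiling(2 * length(ser) / 3), length(ser))]
  sys <- mic$system
  sys$positions <- out$state$positions
  list(ordering = mean(tail_part, na.rm = TRUE), final = sys,
       tails = mic$tails, heads = mic$heads)
}

#' Harmonic bond extra-force for the toy samplers
#'
#' @param bonds two-column index matrix of bonded pairs.
#' @param b0 equilibrium length (nm).
#' @param k force constant (kJ/mol/nm^2).
#' @return Function(positions) -> n x 3 force matrix, suitable as the
#'   `extra_force` argument of [run_langevin()].
#' @export
harmonic_bond_force <- function(bonds, b0 = 0.5, k = 4000) {
  force(bonds); force(b0); force(k)
  function(x) {
    f <- matrix(0, nrow(x), 3L)
    for (bnd in seq_len(nrow(bonds))) {
      i <- bonds[bnd, 1L]; j <- bonds[bnd, 2L]
      d <- x[i, ] - x[j, ]
      r <- sqrt(sum(d^2))
      if (r > 0) {
        fv <- -k * (r - b0) * d / r
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
      }
    }
    f
  }
}

#' Radial core-corona ordering statistic
#'
#' Mean distance of head beads from the whole-assembly center of mass minus
#' the same for tail beads (nm). Positive values mean heads sit peripherally
#' — the micellar core-corona signature.
#'
#' @param positions n x 3 coordinates.
#' @param tails,heads index vectors of the two bead classes.
#' @return Scalar ordering statistic in nm.
#' @export
radial_ordering <- function(positions, tails, heads) {
  com <- center_of_mass(positions)
  dist_to <- function(sel)
    mean(sqrt(rowSums(sweep(positions[sel, , drop = FALSE], 2, com)^2)))
  dist_to(heads) - dist_to(tails)
}

#' Synthetic power-law growth series
#'
#' \eqn{n(t) = t^\alpha e^\eta} with i.i.d. Gaussian log-noise, for
#' exercising the exponent fitter: exponents near 1 mimic diffusion-limited
#' coagulation, exponents near 0.25 the reaction-limited regime.
#'
#' @param alpha power-law exponent (>= 0).
#' @param n_points number of time points (>= 5).
#' @param noise_sd log-normal noise SD (>= 0).
#' @param t_max final time (times are `seq(1, t_max, length.out = n_points)`).
#' @param seed RNG seed.
#' @return A `growth_series`.
#' @export
synth_growth_series <- function(alpha, n_points = 50L, noise_sd = 0,
                                t_max = 100, seed = 1L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (n_points < 5L) stop("need at least 5 points")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  t <- seq(1, t_max, length.out = n_points)
  n <- t^alpha * exp(stats::rnorm(n_points, 0, noise_sd))
  growth_series(t, n)
}

#' Analytic double-well pair potential
#'
#' A quartic two-minimum radial potential used as the known ground truth for
#' umbrella-sampling and WHAM reconstruction tests, with a steep repulsive
#' wall at short range.
#'
#' @param r1,r2 minimum positions (nm).
#' @param barrier barrier height above the wells (kJ/mol).
#' @param wall_sigma repulsive wall scale (nm).
#' @return Function(r) -> energy (kJ/mol), vectorized.
#' @export
make_double_well <- function(r1 = 0.4, r2 = 0.7, barrier = 4, wall_sigma = 0.25) {
  a <- barrier / ((r2 - r1) / 2)^4
  function(r) a * ((r - r1) * (r - r2))^2 + (wall_sigma / r)^12
}
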