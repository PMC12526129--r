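#' Simulation conditions for the toy samplers
#'
#' @param temperature temperature in K (default 310, physiological).
#' @param friction Langevin friction in 1/ps.
#' @param timestep integration time step in ps.
#' @param n_steps number of steps to run.
#' @param seed RNG seed recorded in every output.
#' @return An object of class `sim_conditions`.
#' @export
sim_conditions <- function(temperature = 310, friction = 1, timestep = 0.002,
                           n_steps = 10000L, seed = 1L) {
  if (temperature < 0) stop("temperature must be >= 0")
  if (timestep <= 0) stop("timestep must be positive")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 seed = as.integer(seed)),
            class = "sim_conditions")
}

#' One BAOAB Langevin step
#'
#' Splitting scheme B(half kick) A(half drift) O(Ornstein-Uhlenbeck)
#' A(half drift) B(half kick). With friction and temperature both zero the
#' update reduces to velocity Verlet, so the symplectic limit is recovered.
#'
#' @param state list with `positions` (n x 3, nm), `velocities` (n x 3, nm/ps)
#'   and `forces` (n x 3, kJ/mol/nm, consistent with `positions`).
#' @param system a `particle_system` supplying masses/box (positions in
#'   `state` take precedence).
#' @param table a `pair_table` for force evaluation.
#' @param conditions a `sim_conditions`.
#' @param extra_force optional function(positions) returning an additional
#'   n x 3 force matrix (used for umbrella biases).
#' @return Updated state (with fresh `forces` and `potential`).
#' @export
langevin_step <- function(state, system, table, conditions,
                          extra_force = NULL) {
  m <- system$mass
  dt <- conditions$timestep
  if (!all(is.finite(state$forces))) {
    bad <- which(!apply(is.finite(state$forces), 1, all))[1]
    stop(sprintf("non-finite force on particle %d", bad))
  }
  v <- state$velocities + state$forces * (dt / 2) / m
  x <- state$positions + v * (dt / 2)
  gamma <- conditions$friction
  if (gamma > 0 || conditions$temperature > 0) {
    c1 <- exp(-gamma * dt)
    c2 <- sqrt(pmax(0, (1 - c1^2)) * KB_KJMOL * conditions$temperature / m)
    v <- v * c1 + c2 * matrix(stats::rnorm(length(v)), nrow(v), 3L)
  }
  x <- x + v * (dt / 2)
  system$positions <- x
  f <- compute_forces(system, table)
  if (!is.null(extra_force)) f <- f + extra_force(x)
  v <- v + f * (dt / 2) / m
  list(positions = x, velocities = v, forces = f)
}

#' Run Langevin dynamics and record an observable
#'
#' @inheritParams langevin_step
#' @param observe function(positions) -> numeric scalar/vector recorded every
#'   `stride` steps (default: nothing recorded).
#' @param stride recording stride in steps.
#' @return List with final `state` and matrix `series` of recorded values
#'   (one row per record).
#' @export
run_langevin <- function(system, table, conditions, observe = NULL,
                         stride = 10L, extra_force = NULL) {
  set.seed(conditions$seed)
  n <- n_particles(system)
  f0 <- compute_forces(system, table)
  if (!is.null(extra_force)) f0 <- f0 + extra_force(system$positions)
  state <- list(positions = system$positions,
                velocities = matrix(0, n, 3L), forces = f0)
  # Maxwell-Boltzmann initial velocities
  if (conditions$temperature > 0) {
    sd_v <- sqrt(KB_KJMOL * conditions$temperature / system$mass)
    state$velocities <- sd_v * matrix(stats::rnorm(3 * n), n, 3L)
  }
  series <- NULL
  rec <- list(); ri <- 0L
  for (s in seq_len(conditions$n_steps)) {
    state <- langevin_step(state, system, table, conditions, extra_force)
    if (!is.null(observe) && s %% stride == 0L) {
      ri <- ri + 1L
      rec[[ri]] <- observe(state$positions)
    }
  }
  if (ri > 0L) series <- do.call(rbind, rec)
  list(state = state, series = series, seed = conditions$seed)
}

#' Uniform umbrella window centers
#'
#' Evenly spaced bias centers spanning a reaction-coordinate interval,
#' endpoints included. Defaults follow the standard side-chain analog
#' protocol: 20 windows spanning a center-of-mass separation of 2.5-10 A
#' (0.25-1.0 nm).
#'
#' @param r_min,r_max interval endpoints in nm (`r_max > r_min > 0`).
#' @param n number of windows (>= 2).
#' @return Numeric vector of `n` centers in nm.
#' @export
generate_window_centers <- function(r_min = 0.25, r_max = 1.0, n = 20L) {
  if (n < 2L) stop("need at least 2 windows")
  if (!(r_max > r_min && r_min > 0)) stop("require r_max > r_min > 0")
  seq(r_min, r_max, length.out = n)
}

#' An umbrella window
#'
#' @param center bias center r0 in nm.
#' @param k harmonic force constant in kJ/mol/nm^2 (default 1000).
#' @param samples sampled reaction-coordinate series in nm (post-discard).
#' @param n_discarded number of equilibration samples removed.
#' @param seed RNG seed used to generate the samples.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k = 1000, samples, n_discarded = 0L,
                            seed = NA_integer_) {
  if (k <= 0) stop("force constant must be positive")
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("window has no samples after discard")
  if (any(samples <= 0)) stop("reaction-coordinate samples must be positive")
  structure(list(center = center, k = k, samples = samples,
                 n_discarded = as.integer(n_discarded),
                 seed = as.integer(seed)),
            class = "umbrella_window")
}

#' Biased (umbrella) sampling of a pair COM separation
#'
#' Samples the center-of-mass separation between two disjoint particle
#' selections under the hybrid model plus a harmonic bias
#' \eqn{\frac k2 (r - r_0)^2}, using Langevin dynamics. The first
#' `discard_frac` of recorded samples is dropped as equilibration.
#'
#' @param system a `particle_system`.
#' @param table a `pair_table` for the unbiased forces.
#' @param sel_a,sel_b integer index vectors of the two groups (disjoint,
#'   non-empty).
#' @param center bias center r0 (nm).
#' @param k force constant (kJ/mol/nm^2), default 1000.
#' @param conditions a `sim_conditions`.
#' @param stride sample recording stride (steps).
#' @param discard_frac fraction of initial samples discarded (default 0.1).
#' @return An `umbrella_window`.
#' @export
run_umbrella_window <- function(system, table, sel_a, sel_b, center, k = 1000,
                                conditions = sim_conditions(),
                                stride = 10L, discard_frac = 0.1) {
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("both selections must be non-empty")
  if (length(intersect(sel_a, sel_b)) > 0L)
    stop("selections must be disjoint")
  ma <- system$mass[sel_a]; mb <- system$mass[sel_b]
  wa <- ma / sum(ma); wb <- mb / sum(mb)
  com_sep <- function(x) {
    d <- minimum_image(colSums(x[sel_a, , drop = FALSE] * wa) -
                         colSums(x[sel_b, , drop = FALSE] * wb), system$box)
    sqrt(sum(d^2))
  }
  bias_force <- function(x) {
    d <- minimum_image(colSums(x[sel_a, , drop = FALSE] * wa) -
                         colSums(x[sel_b, , drop = FALSE] * wb), system$box)
    r <- sqrt(sum(d^2))
    f <- matrix(0, nrow(x), 3L)
    if (r > 0) {
      g <- -k * (r - center) * d / r  # force on group-a COM
      f[sel_a, ] <- matrix(g, length(sel_a), 3L, byrow = TRUE) * wa
      f[sel_b, ] <- -matrix(g, length(sel_b), 3L, byrow = TRUE) * wb
    }
    f
  }
  out <- run_langevin(system, table, conditions = conditions,
                      observe = com_sep, stride = stride,
                      extra_force = bias_force)
  samples <- as.numeric(out$series)
  nd <- floor(discard_frac * length(samples))
  umbrella_window(center, k, samples[(nd + 1):length(samples)],
                  n_discarded = nd, seed = conditions$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Metropolis sampling of a scalar pair separation
#'
#' One-dimensional Metropolis Monte Carlo on the separation coordinate `r`
#' with target density proportional to
#' \eqn{\exp[-\beta (U(r) + \frac k2 (r - r_0)^2)]}. No \eqn{r^2} Jacobian is
#' included, matching the default no-Jacobian WHAM convention, so the
#' reconstructed profile estimates `U(r)` directly.
#'
#' @param potential function(r) -> energy kJ/mol.
#' @param center bias center r0 (nm); `NA` for unbiased sampling.
#' @param k force constant (kJ/mol/nm^2); ignored when `center` is `NA`.
#' @param temperature K.
#' @param n_samples samples to return after discard.
#' @param step_sd proposal standard deviation (nm).
#' @param r_init initial coordinate (defaults to `center` or 0.5 nm).
#' @param discard_frac equilibration fraction discarded.
#' @param seed RNG seed.
#' @return An `umbrella_window` (for unbiased runs `k` is stored as a tiny
#'   positive placeholder and `center` as `NA`).
#' @export
metropolis_window <- function(potential, center = NA, k = 1000,
                              temperature = 310, n_samples = 2000L,
                              step_sd = 0.02, r_init = NULL,
                              discard_frac = 0.1, seed = 1L) {
  set.seed(seed)
  beta <- 1 / (KB_KJMOL * temperature)
  biased <- !is.na(center)
  u_tot <- function(r) {
    u <- potential(r)
    if (biased) u <- u + 0.5 * k * (r - center)^2
    u
  }
  n_total <- ceiling(n_samples / (1 - discard_frac))
  r <- if (!is.null(r_init)) r_init else if (biased) center else 0.5
  u <- u_tot(r)
  out <- numeric(n_total)
  for (s in seq_len(n_total)) {
    rp <- r + stats::rnorm(1, 0, step_sd)
    if (rp > 0) {
      up <- u_tot(rp)
      if (is.finite(up) && log(stats::runif(1)) < -beta * (up - u)) {
        r <- rp; u <- up
      }
    }
    out[s] <- r
  }
  nd <- n_total - n_samples
  umbrella_window(if (biased) center else NA_real_,
                  if (biased) k else .Machine$double.eps,
                  out[(nd + 1):n_total], n_discarded = nd, seed = seed)
}
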