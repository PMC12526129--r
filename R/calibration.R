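#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of a set of particles from their
#' center of mass — the standard compaction metric used to calibrate
#' coarse-grained interaction strengths against reference ensembles.
#'
#' @param positions n x 3 coordinate matrix (nm).
#' @param masses particle masses (default equal weights).
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(positions, masses = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 1L) stop("empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  if (any(masses <= 0)) stop("masses must be positive")
  com <- center_of_mass(positions, masses)
  d2 <- rowSums(sweep(positions, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Distance between two empirical distributions
#'
#' Default metric is the 1-D Wasserstein (earth mover's) distance, which is
#' robust to binning and has the closed form `|delta|` for a pure location
#' shift. Alternatives: the Kolmogorov-Smirnov statistic and the absolute
#' difference of density-mode (peak) positions.
#'
#' @param a,b numeric sample vectors (non-empty).
#' @param metric one of `"wasserstein"`, `"ks"`, `"peak"`.
#' @return Non-negative scalar; 0 iff the empirical distributions coincide
#'   (for the default metric).
#' @export
distribution_distance <- function(a, b, metric = c("wasserstein", "ks", "peak")) {
  metric <- match.arg(metric)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  switch(metric,
    wasserstein = {
      if (length(a) == length(b)) {
        mean(abs(sort(a) - sort(b)))
      } else {
        m <- 512L
        qs <- (seq_len(m) - 0.5) / m
        mean(abs(stats::quantile(a, qs, type = 4, names = FALSE) -
                   stats::quantile(b, qs, type = 4, names = FALSE)))
      }
    },
    ks = unname(suppressWarnings(stats::ks.test(a, b)$statistic)),
    peak = {
      da <- stats::density(a); db <- stats::density(b)
      abs(da$x[which.max(da$y)] - db$x[which.max(db$y)])
    })
}

#' Fit Lennard-Jones cross parameters against a reference profile
#'
#' Stage-one parameterization: derivative-free (Nelder-Mead) minimization of
#' \eqn{w_d |\Delta \mathrm{depth}| + w_p |\Delta \mathrm{position}|}
#' between the first minimum of a candidate profile (produced by
#' `pmf_generator(epsilon, sigma)`) and that of a reference profile.
#' Parameters are clipped to `lower`/`upper`; candidate profiles without a
#' first minimum incur a large penalty rather than aborting the search.
#'
#' @param reference a `pmf_profile` with a first minimum.
#' @param pmf_generator function(epsilon, sigma) -> `pmf_profile`; must be
#'   deterministic under its own seed policy.
#' @param init length-2 numeric start `c(epsilon, sigma)` (kJ/mol, nm).
#' @param lower,upper length-2 bounds on `c(epsilon, sigma)`.
#' @param w_depth,w_pos objective weights; defaults 1 per kJ/mol and 10 per
#'   nm, so a 0.1 nm position miss costs as much as a 1 kJ/mol depth miss.
#' @param tol relative convergence tolerance passed to [stats::optim()].
#' @param max_eval evaluation budget.
#' @param smoothing smoothing passed to [first_minimum()].
#' @return Object of class `fit_result`: fitted `epsilon`, `sigma`,
#'   `objective`, `evaluations`, `converged`, and the evaluation `trace`.
#' @export
fit_cross_lj <- function(reference, pmf_generator, init = c(1, 0.45),
                         lower = c(0.05, 0.2), upper = c(10, 0.8),
                         w_depth = 1, w_pos = 10, tol = 1e-6,
                         max_eval = 500L, smoothing = 0L) {
  ref_min <- first_minimum(reference, smoothing)
  if (!ref_min$found) stop("reference profile has no first minimum")
  trace <- list(); n_eval <- 0L
  objective <- function(par) {
    par <- pmin(pmax(par, lower), upper)
    prof <- tryCatch(pmf_generator(par[1], par[2]),
                     error = function(e)
                       stop(sprintf("pmf_generator failed at (epsilon=%.4g, sigma=%.4g): %s",
                                    par[1], par[2], conditionMessage(e))))
    m <- first_minimum(prof, smoothing)
    val <- if (!m$found) {
      1e3 + w_depth * ref_min$depth  # heavily penalized, not fatal
    } else {
      w_depth * abs(m$depth - ref_min$depth) +
        w_pos * abs(m$position - ref_min$position)
    }
    n_eval <<- n_eval + 1L
    trace[[n_eval]] <<- c(epsilon = par[1], sigma = par[2], objective = val)
    val
  }
  opt <- stats::optim(init, objective, method = "Nelder-Mead",
                      control = list(reltol = tol, maxit = max_eval))
  par <- pmin(pmax(opt$par, lower), upper)
  structure(
    list(epsilon = par[1], sigma = par[2], objective = opt$value,
         evaluations = n_eval, converged = opt$convergence == 0,
         trace = do.call(rbind, trace)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: epsilon = %.4g kJ/mol, sigma = %.4g nm, objective = %.4g (%d evaluations%s)\n",
              x$epsilon, x$sigma, x$objective, x$evaluations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Calibrate a well-depth scaling factor against a reference Rg ensemble
#'
#' Stage-two parameterization: scans a grid of candidate scaling factors,
#' generates a radius-of-gyration ensemble for each, and selects the
#' candidate whose ensemble is closest to the reference under the chosen
#' distribution metric. Grid search matches the coarse granularity at which
#' such factors are reported (e.g. 0.2, 0.8); ties break toward the smaller
#' candidate so the result is independent of candidate ordering.
#'
#' @param reference numeric vector of reference Rg samples (nm).
#' @param ensemble_generator function(epsilon) -> numeric Rg samples.
#' @param candidates numeric vector of >= 2 candidate factors in (0, 2].
#' @param metric passed to [distribution_distance()].
#' @return List with `selected` (the chosen factor) and `table`
#'   (data frame candidate vs distance, in scan order sorted by candidate).
#' @export
calibrate_scaling_factor <- function(reference, ensemble_generator,
                                     candidates = seq(0.1, 1.0, by = 0.1),
                                     metric = "wasserstein") {
  candidates <- as.numeric(candidates)
  if (length(candidates) < 2L) stop("need at least 2 candidates")
  if (any(candidates <= 0 | candidates > 2))
    stop("candidates must lie in (0, 2]")
  ord <- order(candidates)
  candidates <- candidates[ord]
  dist <- vapply(candidates, function(eps) {
    ens <- tryCatch(ensemble_generator(eps),
                    error = function(e)
                      stop(sprintf("ensemble generator failed at candidate %.4g: %s",
                                   eps, conditionMessage(e))))
    distribution_distance(reference, ens, metric = metric)
  }, 0)
  sel <- candidates[which.min(dist)]  # which.min takes the first (smallest) on ties
  list(selected = sel,
       table = data.frame(candidate = candidates, distance = dist))
}

#' Monte Carlo radius-of-gyration ensemble for a toy bead polymer
#'
#' Samples conformations of a freely jointed bead chain (harmonic bonds,
#' Lennard-Jones attraction between non-bonded bead pairs whose well depth is
#' multiplied by `scale`) by single-bead-displacement Metropolis moves, and
#' records the radius of gyration. This is the desk-scale surrogate for the
#' polymer ensembles used to calibrate coarse-grained scaling factors:
#' stronger cohesion compacts the chain and shifts the Rg distribution down.
#'
#' @param n_beads chain length (default 10).
#' @param scale multiplicative factor on the bead-bead well depth.
#' @param epsilon base well depth (kJ/mol) before scaling.
#' @param sigma bead diameter (nm).
#' @param bond_length equilibrium bond length (nm).
#' @param bond_k bond force constant (kJ/mol/nm^2).
#' @param temperature K.
#' @param n_sweeps MC sweeps (one attempted move per bead per sweep).
#' @param sample_stride sweeps between recorded Rg values.
#' @param discard_frac equilibration fraction discarded.
#' @param step_sd displacement proposal SD (nm).
#' @param seed RNG seed.
#' @return Numeric vector of Rg samples (nm).
#' @export
polymer_rg_ensemble <- function(n_beads = 10L, scale = 1, epsilon = 4,
                                sigma = 0.47, bond_length = 0.47,
                                bond_k = 500, temperature = 310,
                                n_sweeps = 4000L, sample_stride = 4L,
                                discard_frac = 0.2, step_sd = 0.06,
                                seed = 1L) {
  set.seed(seed)
  beta <- 1 / (KB_KJMOL * temperature)
  eps_eff <- epsilon * scale
  x <- cbind((seq_len(n_beads) - 1) * bond_length, 0, 0)

  chain_energy <- function(pos) {
    b <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                         pos[-n_beads, , drop = FALSE])^2))
    e <- 0.5 * bond_k * sum((b - bond_length)^2)
    if (n_beads > 2L) {
      d <- stats::dist(pos)
      # drop bonded (adjacent) pairs from the nonbonded sum
      dm <- as.matrix(d)
      nb <- dm[upper.tri(dm)]
      adj <- abs(row(dm) - col(dm)) == 1L
      nb <- dm[upper.tri(dm) & !adj]
      sr6 <- (sigma / nb)^6
      e <- e + sum(4 * eps_eff * (sr6^2 - sr6))
    }
    e
  }
  others_list <- lapply(seq_len(n_beads), function(i)
    setdiff(seq_len(n_beads), (i - 1L):(i + 1L)))
  bead_energy <- function(pos, i, xi) {
    e <- 0
    if (i > 1L) e <- e + 0.5 * bond_k * (sqrt(sum((xi - pos[i - 1L, ])^2)) - bond_length)^2
    if (i < n_beads) e <- e + 0.5 * bond_k * (sqrt(sum((xi - pos[i + 1L, ])^2)) - bond_length)^2
    others <- others_list[[i]]
    if (length(others) > 0L) {
      po <- pos[others, , drop = FALSE]
      r <- sqrt((po[, 1] - xi[1])^2 + (po[, 2] - xi[2])^2 + (po[, 3] - xi[3])^2)
      sr6 <- (sigma / r)^6
      e <- e + sum(4 * eps_eff * (sr6^2 - sr6))
    }
    e
  }
  # pivot move: rotate the tail beyond a random bead by a random rotation
  pivot <- function(pos) {
    p <- sample(2:(n_beads - 1L), 1L)
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- stats::runif(1, -pi, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    tail_idx <- (p + 1L):n_beads
    rel <- sweep(pos[tail_idx, , drop = FALSE], 2, pos[p, ])
    pos[tail_idx, ] <- sweep(rel %*% t(R), 2, pos[p, ], `+`)
    pos
  }

  e_cur <- chain_energy(x)
  out <- numeric(0)
  for (sw in seq_len(n_sweeps)) {
    for (i in seq_len(n_beads)) {
      xi_new <- x[i, ] + stats::rnorm(3, 0, step_sd)
      de <- bead_energy(x, i, xi_new) - bead_energy(x, i, x[i, ])
      if (is.finite(de) && log(stats::runif(1)) < -beta * de) {
        x[i, ] <- xi_new
        e_cur <- e_cur + de
      }
    }
    xp <- pivot(x)
    ep <- chain_energy(xp)
    if (is.finite(ep) && log(stats::runif(1)) < -beta * (ep - e_cur)) {
      x <- xp; e_cur <- ep
    }
    if (sw > n_sweeps * discard_frac && sw %% sample_stride == 0L)
      out <- c(out, radius_of_gyration(x))
  }
  out
}
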