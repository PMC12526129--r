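#' A potential-of-mean-force profile
#'
#' Free energy versus pair separation on a strictly increasing grid of bin
#' centers, with per-bin sample counts and a recorded zero convention.
#'
#' @param r strictly increasing bin centers (nm).
#' @param free_energy free energy values F(r) in kJ/mol (`NA` allowed in
#'   unpopulated bins).
#' @param temperature temperature (K) the profile refers to.
#' @param counts per-bin sample counts (default 1 in every bin, e.g. for
#'   analytic profiles).
#' @param zero one of `"zero-at-rmax"` (free energy measured relative to the
#'   largest well-sampled separation, the binding-well convention) or
#'   `"min-is-zero"`.
#' @return Object of class `pmf_profile`.
#' @export
pmf_profile <- function(r, free_energy, temperature = 310, counts = NULL,
                        zero = c("zero-at-rmax", "min-is-zero")) {
  zero <- match.arg(zero)
  r <- as.numeric(r); free_energy <- as.numeric(free_energy)
  if (length(r) != length(free_energy))
    stop("r and free_energy must have equal length")
  if (any(diff(r) <= 0)) stop("grid must be strictly increasing")
  counts <- if (is.null(counts)) rep(1, length(r)) else as.numeric(counts)
  if (length(counts) != length(r))
    stop("counts must match the grid length")
  if (any(counts > 0 & !is.finite(free_energy)))
    stop("free energy must be finite wherever counts > 0")
  f <- normalize_pmf(free_energy, counts, zero)
  structure(list(r = r, free_energy = f, temperature = temperature,
                 counts = counts, zero = zero),
            class = "pmf_profile")
}

normalize_pmf <- function(f, counts, zero) {
  ok <- counts > 0 & is.finite(f)
  if (!any(ok)) return(f)
  ref <- switch(zero,
                "zero-at-rmax" = f[max(which(ok))],
                "min-is-zero" = min(f[ok]))
  f - ref
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- x$counts > 0 & is.finite(x$free_energy)
  cat(sprintf("pmf_profile: %d bins over %.3f-%.3f nm (%d populated), T = %g K, zero = %s\n",
              length(x$r), min(x$r), max(x$r), sum(ok), x$temperature, x$zero))
  invisible(x)
}

#' Weighted histogram analysis of umbrella windows
#'
#' Self-consistent WHAM over binned window histograms. Iteration alternates
#' between the unbiased bin probabilities
#' \deqn{p_m = \frac{\sum_w n_{wm}}{\sum_w N_w e^{\beta(f_w - b_w(r_m))}}}
#' and the window free-energy offsets
#' \eqn{f_w = -k_BT \ln \sum_m p_m e^{-\beta b_w(r_m)}}, stopping when the
#' largest change in any offset falls below `tol`. A single unbiased window
#' reduces exactly to Boltzmann inversion of its histogram.
#'
#' @param windows list of `umbrella_window` objects (>= 1).
#' @param r_min,r_max,bin_width histogram grid (defaults 0.25-1.0 nm at
#'   0.01 nm resolution).
#' @param temperature K.
#' @param tol convergence tolerance on the window offsets (kJ/mol).
#' @param max_iter iteration cap.
#' @param jacobian logical; add the radial entropy correction
#'   \eqn{+2 k_BT \ln r} appropriate when samples come from an isotropic 3-D
#'   separation vector. Off by default (scalar-coordinate samplers need none).
#' @param zero zero convention passed to [pmf_profile()].
#' @return A `pmf_profile` with attributes `offsets` (per-window free
#'   energies) and `residuals` (per-iteration convergence residuals).
#' @export
wham <- function(windows, r_min = 0.25, r_max = 1.0, bin_width = 0.01,
                 temperature = 310, tol = 1e-7, max_iter = 1e5,
                 jacobian = FALSE, zero = "zero-at-rmax") {
  if (length(windows) < 1L) stop("need at least one window")
  stopifnot(all(vapply(windows, inherits, TRUE, "umbrella_window")))
  beta <- 1 / (KB_KJMOL * temperature)
  edges <- seq(r_min, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers); nw <- length(windows)

  counts <- matrix(0, nw, nb)
  for (w in seq_len(nw)) {
    s <- windows[[w]]$samples
    s <- s[s >= edges[1] & s < edges[length(edges)]]
    if (length(s) > 0)
      counts[w, ] <- tabulate(findInterval(s, edges), nbins = nb)
  }
  # overlap check along the window chain, sorted by bias center
  if (nw > 1L) {
    ord <- order(vapply(windows, function(w) w$center %||% NA_real_, 0))
    for (k in seq_len(nw - 1L)) {
      a <- ord[k]; b <- ord[k + 1L]
      if (!any(counts[a, ] > 0 & counts[b, ] > 0))
        stop(sprintf(
          "non-overlapping window chain: no shared populated bin between windows centered at %.3f and %.3f nm",
          windows[[a]]$center, windows[[b]]$center))
    }
  }

  bias <- matrix(0, nw, nb)
  for (w in seq_len(nw)) {
    ctr <- windows[[w]]$center
    if (!is.na(ctr))
      bias[w, ] <- 0.5 * windows[[w]]$k * (centers - ctr)^2
  }
  N <- rowSums(counts)
  num <- colSums(counts)
  f <- numeric(nw)
  residuals <- numeric(0)
  expb <- exp(-beta * bias)  # nw x nb
  for (it in seq_len(max_iter)) {
    denom <- colSums((N * exp(beta * f)) * expb)  # length nb
    p <- ifelse(denom > 0, num / denom, 0)
    f_new <- -log(as.numeric(expb %*% p)) / beta
    f_new <- f_new - f_new[1]
    res <- max(abs(f_new - f))
    residuals <- c(residuals, res)
    f <- f_new
    if (res < tol) break
  }
  if (residuals[length(residuals)] >= tol && length(residuals) >= max_iter)
    stop(sprintf("WHAM did not converge in %d iterations (last residual %.3g kJ/mol)",
                 as.integer(max_iter), residuals[length(residuals)]))

  denom <- colSums((N * exp(beta * f)) * expb)
  p <- ifelse(denom > 0 & num > 0, num / denom, NA_real_)
  F <- -log(p) / beta
  if (jacobian) F <- F + 2 * log(centers) / beta
  prof <- pmf_profile(centers, ifelse(is.na(F), NA_real_, F),
                      temperature = temperature, counts = num, zero = zero)
  attr(prof, "offsets") <- f
  attr(prof, "residuals") <- residuals
  prof
}

#' Descriptor of the first free-energy minimum
#' @param depth positive well depth (kJ/mol) relative to the large-r plateau.
#' @param position minimum position (nm).
#' @param found logical; `FALSE` encodes the distinguished "no minimum"
#'   result for monotone profiles.
#' @return Object of class `minimum_descriptor`.
#' @export
minimum_descriptor <- function(depth, position, found = TRUE) {
  structure(list(depth = depth, position = position, found = found),
            class = "minimum_descriptor")
}

#' @export
print.minimum_descriptor <- function(x, ...) {
  if (!x$found) cat("no first minimum found\n")
  else cat(sprintf("first minimum: depth %.4g kJ/mol at %.4f nm\n",
                   x$depth, x$position))
  invisible(x)
}

#' Locate the first free-energy minimum of a profile
#'
#' Scans populated bins from small separation for the first discrete local
#' minimum (after optional moving-average smoothing), then refines the
#' position by a parabola through the minimum bin and its neighbors. Depth is
#' reported as the free energy at the minimum measured relative to the
#' profile value at the largest well-sampled separation (the dissociated
#' plateau), as a positive magnitude.
#'
#' @param pmf a `pmf_profile` with >= 5 populated bins.
#' @param smoothing moving-average width in bins (0 or 1 = none; use odd
#'   widths such as 3).
#' @return A `minimum_descriptor`; `found = FALSE` when the profile is
#'   monotone with no interior minimum.
#' @export
first_minimum <- function(pmf, smoothing = 0L) {
  ok <- pmf$counts > 0 & is.finite(pmf$free_energy)
  if (sum(ok) < 5L) stop("need at least 5 populated bins")
  r <- pmf$r[ok]; f <- pmf$free_energy[ok]
  fs <- f
  if (smoothing > 1L) {
    kern <- rep(1 / smoothing, smoothing)
    fs <- stats::filter(f, kern, sides = 2)
    fs[is.na(fs)] <- f[is.na(fs)]
    fs <- as.numeric(fs)
  }
  plateau <- f[length(f)]
  n <- length(fs)
  for (i in 2:(n - 1)) {
    if (fs[i] < fs[i - 1] && fs[i] <= fs[i + 1]) {
      # parabolic sub-bin refinement on the unsmoothed values
      x <- r[(i - 1):(i + 1)]; y <- f[(i - 1):(i + 1)]
      dd <- (y[3] - 2 * y[2] + y[1])
      pos <- if (dd > 0) {
        x[2] - (x[3] - x[1]) / 2 * (y[3] - y[1]) / (2 * dd)
      } else x[2]
      pos <- min(max(pos, x[1]), x[3])
      fmin <- if (dd > 0) y[2] - (y[3] - y[1])^2 / (8 * dd) else y[2]
      return(minimum_descriptor(depth = max(0, plateau - fmin),
                                position = pos))
    }
  }
  minimum_descriptor(NA_real_, NA_real_, found = FALSE)
}

#' Deviation between the first minima of two profiles
#'
#' Absolute differences in well depth and position between a model profile
#' and a reference — the per-pair quantities whose averages summarize how
#' well fitted cross terms reproduce reference free-energy curves.
#'
#' @param model,reference `pmf_profile` objects, each with a first minimum.
#' @param smoothing smoothing passed to [first_minimum()].
#' @return List with `d_depth` (kJ/mol) and `d_position` (nm).
#' @export
pmf_deviation <- function(model, reference, smoothing = 0L) {
  mm <- first_minimum(model, smoothing)
  mr <- first_minimum(reference, smoothing)
  if (!mm$found) stop("model profile has no first minimum")
  if (!mr$found) stop("reference profile has no first minimum")
  list(d_depth = abs(mm$depth - mr$depth),
       d_position = abs(mm$position - mr$position))
}
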