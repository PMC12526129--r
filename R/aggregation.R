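#' Single-linkage chain clustering
#'
#' Chains are linked whenever any inter-chain particle distance
#' (minimum-image when the system has a box) falls below `cutoff`; clusters
#' are the connected components of the resulting chain contact graph, so the
#' partition is transitive and invariant under chain relabeling, and a larger
#' cutoff can only merge, never split, clusters.
#'
#' @param system a `particle_system`.
#' @param chains optional character vector restricting which chain ids are
#'   clustered (default: all).
#' @param cutoff contact distance in nm (default 0.6).
#' @param frame optional frame index stored in the result.
#' @return Object of class `cluster_set`: list with `clusters` (list of chain
#'   id vectors, largest first), `membership` (named integer vector
#'   chain -> cluster), and `frame`.
#' @export
find_clusters <- function(system, chains = NULL, cutoff = 0.6, frame = NA_integer_) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ids <- unique(system$chain)
  if (!is.null(chains)) ids <- ids[ids %in% chains]
  if (length(ids) == 0L) stop("empty chain selection")
  sel <- system$chain %in% ids
  pos <- system$positions[sel, , drop = FALSE]
  ch <- factor(system$chain[sel], levels = ids)
  n <- nrow(pos)
  # all inter-chain particle pairs within cutoff
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  keep <- ch[i] != ch[j]
  i <- i[keep]; j <- j[keep]
  edges <- NULL
  if (length(i) > 0L) {
    d <- minimum_image(pos[i, , drop = FALSE] - pos[j, , drop = FALSE],
                       system$box)
    close <- rowSums(d^2) < cutoff^2
    if (any(close))
      edges <- unique(cbind(as.integer(ch[i[close]]), as.integer(ch[j[close]])))
  }
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  clusters <- split(ids, comp)
  clusters <- clusters[order(-lengths(clusters))]
  names(clusters) <- NULL
  membership <- integer(length(ids)); names(membership) <- ids
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  structure(list(clusters = clusters, membership = membership, frame = frame),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d chain(s) in %d cluster(s); largest has %d\n",
              length(x$membership), length(x$clusters),
              length(x$clusters[[1]])))
  invisible(x)
}

#' A cluster growth series
#'
#' @param times time points (any consistent unit; must be positive for
#'   power-law fitting).
#' @param size largest-cluster size in chains at each time.
#' @param n_total optional total chain count, used to derive the fraction.
#' @return Object of class `growth_series` with fields `times`, `size`,
#'   `fraction`, and fit slots (`alpha`, `alpha_se`, `fit_range`) filled by
#'   [fit_growth_exponent()].
#' @export
growth_series <- function(times, size, n_total = NULL) {
  times <- as.numeric(times); size <- as.numeric(size)
  if (length(times) != length(size)) stop("times and size lengths differ")
  if (any(size <= 0)) stop("cluster size must be positive")
  structure(list(times = times, size = size,
                 fraction = if (!is.null(n_total)) size / n_total else NULL,
                 alpha = NA_real_, alpha_se = NA_real_, fit_range = NULL),
            class = "growth_series")
}

#' Fit a cluster-growth power-law exponent
#'
#' Ordinary least squares on the log-log transformed series
#' \eqn{\ln n = \alpha \ln t + c}: exponents near 1 indicate
#' diffusion-limited coagulation, much smaller exponents a reaction-limited
#' regime with an activation barrier at contact.
#'
#' @param series a `growth_series` (or list with `times` and `size`).
#' @param fit_range optional length-2 time interval to fit over.
#' @return The series with `alpha`, `alpha_se`, and `fit_range` filled.
#' @export
fit_growth_exponent <- function(series, fit_range = NULL) {
  t <- series$times; n <- series$size
  if (!is.null(fit_range)) {
    keep <- t >= fit_range[1] & t <= fit_range[2]
    t <- t[keep]; n <- n[keep]
  }
  if (length(t) < 5L) stop("need at least 5 points in the fit range")
  if (any(t <= 0) || any(n <= 0))
    stop("power-law fit requires strictly positive times and sizes")
  fit <- stats::lm(log(n) ~ log(t))
  series$alpha <- unname(stats::coef(fit)[2])
  # noise-free series are legitimate input; silence the perfect-fit warning
  series$alpha_se <- unname(sqrt(diag(suppressWarnings(stats::vcov(fit))))[2])
  series$fit_range <- if (is.null(fit_range)) range(series$times) else fit_range
  series
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf("growth_series: %d points", length(x$times)))
  if (is.finite(x$alpha))
    cat(sprintf(", alpha = %.3f +/- %.3f over [%g, %g]",
                x$alpha, x$alpha_se, x$fit_range[1], x$fit_range[2]))
  cat("\n")
  invisible(x)
}

#' Center of mass of a (possibly wrapped) cluster
#'
#' Unwraps the cluster about its first particle via the minimum-image
#' convention before mass weighting; correct for clusters whose extent is
#' below half the box edge, which is the regime where a cluster COM is
#' meaningful at all.
#'
#' @param positions n x 3 coordinates (nm).
#' @param masses particle masses.
#' @param box box lengths or `NULL`.
#' @return Length-3 COM vector (in the image of the anchor particle).
#' @export
cluster_com <- function(positions, masses = NULL, box = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  anchor <- positions[1, ]
  rel <- minimum_image(sweep(positions, 2, anchor), box)
  anchor + colSums(rel * masses) / sum(masses)
}

#' Encounter events in a distance series
#'
#' Maximal time intervals during which the distance stays below the
#' encounter threshold. Units are whatever the series carries, as long as
#' `threshold` matches.
#'
#' @param times time points (sorted).
#' @param d distances (>= 0), same length.
#' @param threshold encounter distance.
#' @return Data frame with one row per event: `start`, `end` (times) and
#'   `min_distance`.
#' @export
encounter_events <- function(times, d, threshold) {
  if (any(d < 0)) stop("distances must be non-negative")
  below <- d < threshold
  if (!any(below)) return(data.frame(start = numeric(0), end = numeric(0),
                                     min_distance = numeric(0)))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ev <- which(r$values)
  data.frame(
    start = times[starts[ev]],
    end = times[ends[ev]],
    min_distance = vapply(ev, function(k) min(d[starts[k]:ends[k]]), 0))
}

#' Inter-cluster COM distance series with encounter/fusion bookkeeping
#'
#' Tracks the mass-weighted, minimum-image center-of-mass distance between
#' two fixed chain groups across an ordered frame sequence; flags encounter
#' events (intervals below `threshold`) and fusion frames (any inter-group
#' particle contact below `fuse_cutoff`, i.e. the two groups would single-link
#' into one cluster).
#'
#' @param frames list of `particle_system` frames (same topology).
#' @param chains_a,chains_b chain id vectors of the two tracked clusters
#'   (non-empty, disjoint).
#' @param threshold encounter distance in nm.
#' @param fuse_cutoff contact cutoff in nm used for fusion detection.
#' @param times optional time stamps (default frame index).
#' @return Object of class `cluster_pair_series`: `times`, `distance` (nm),
#'   `threshold`, `encounters` (data frame), `fusions` (time stamps).
#' @export
com_distance_series <- function(frames, chains_a, chains_b, threshold = 3.0,
                                fuse_cutoff = 0.6, times = NULL) {
  if (length(chains_a) == 0L || length(chains_b) == 0L)
    stop("both tracked clusters must be non-empty")
  if (length(intersect(chains_a, chains_b)) > 0L)
    stop("tracked clusters must be disjoint")
  nf <- length(frames)
  times <- if (is.null(times)) seq_len(nf) else as.numeric(times)
  d <- numeric(nf); fused <- logical(nf)
  for (f in seq_len(nf)) {
    sys <- frames[[f]]
    ia <- which(sys$chain %in% chains_a)
    ib <- which(sys$chain %in% chains_b)
    if (length(ia) == 0L || length(ib) == 0L)
      stop(sprintf("tracked cluster empty in frame %d", f))
    ca <- cluster_com(sys$positions[ia, , drop = FALSE], sys$mass[ia], sys$box)
    cb <- cluster_com(sys$positions[ib, , drop = FALSE], sys$mass[ib], sys$box)
    d[f] <- sqrt(sum(minimum_image(ca - cb, sys$box)^2))
    dmin2 <- min(outer_pair_dist2(sys$positions[ia, , drop = FALSE],
                                  sys$positions[ib, , drop = FALSE], sys$box))
    fused[f] <- dmin2 < fuse_cutoff^2
  }
  structure(list(times = times, distance = d, threshold = threshold,
                 encounters = encounter_events(times, d, threshold),
                 fusions = times[fused]),
            class = "cluster_pair_series")
}

# squared minimum-image distances between two coordinate sets
outer_pair_dist2 <- function(a, b, box = NULL) {
  na <- nrow(a); nb <- nrow(b)
  d2 <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    d <- minimum_image(sweep(a, 2, b[j, ]), box)
    d2[, j] <- rowSums(d^2)
  }
  d2
}
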