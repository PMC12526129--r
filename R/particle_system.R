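#' Construct a particle system
#'
#' A `particle_system` holds everything the hybrid energy model needs about a
#' configuration: coordinates in nm, a per-particle resolution tag (`"UA"` for
#' united-atom sites, `"CG"` for coarse-grained beads), type labels used for
#' parameter lookup, charges, masses, chain/residue bookkeeping, an optional
#' orthorhombic periodic box, and a symmetric list of bonded exclusions.
#'
#' @param positions numeric matrix, n x 3, coordinates in nm.
#' @param resolution character vector of `"UA"` / `"CG"` tags, one per particle.
#' @param type character vector of particle type labels (pair-table keys).
#' @param charge numeric vector of charges in elementary units (default 0).
#' @param mass numeric vector of masses in amu (default 1).
#' @param chain chain identifiers, one per particle (default one chain).
#' @param resid integer residue indices (default `1`).
#' @param resname residue name labels (default `""`).
#' @param box optional length-3 numeric vector of box edge lengths in nm; `NULL`
#'   for a non-periodic system.
#' @param exclusions two-column integer matrix of particle index pairs excluded
#'   from nonbonded sums; stored symmetrically.
#'
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(positions, resolution, type,
                            charge = NULL, mass = NULL,
                            chain = NULL, resid = NULL, resname = NULL,
                            box = NULL, exclusions = NULL) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  if (ncol(positions) != 3L)
    stop("`positions` must be an n x 3 matrix")
  n <- nrow(positions)
  if (n < 1L) stop("a particle system needs at least one particle")
  if (!all(is.finite(positions)))
    stop("positions must be finite")

  resolution <- as.character(resolution)
  if (length(resolution) == 1L) resolution <- rep(resolution, n)
  if (length(resolution) != n)
    stop("`resolution` must have one entry per particle")
  if (!all(resolution %in% c("UA", "CG")))
    stop("resolution tags must be \"UA\" or \"CG\"")

  type <- as.character(type)
  if (length(type) == 1L) type <- rep(type, n)
  if (length(type) != n) stop("`type` must have one entry per particle")

  charge <- if (is.null(charge)) numeric(n) else rep_len(as.numeric(charge), n)
  mass <- if (is.null(mass)) rep(1, n) else rep_len(as.numeric(mass), n)
  if (any(mass <= 0)) stop("masses must be positive")
  chain <- if (is.null(chain)) rep("A", n) else rep_len(as.character(chain), n)
  resid <- if (is.null(resid)) rep(1L, n) else rep_len(as.integer(resid), n)
  resname <- if (is.null(resname)) rep("", n) else rep_len(as.character(resname), n)

  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      stop("`box` must be three strictly positive edge lengths (nm)")
  }

  if (is.null(exclusions)) {
    exclusions <- matrix(integer(0), ncol = 2L)
  } else {
    exclusions <- as.matrix(exclusions)
    if (ncol(exclusions) != 2L) stop("`exclusions` must be a two-column matrix")
    storage.mode(exclusions) <- "integer"
    if (nrow(exclusions) > 0L) {
      if (any(exclusions < 1L | exclusions > n))
        stop("exclusion indices out of range")
      # store symmetrically and deduplicated
      exclusions <- unique(rbind(exclusions, exclusions[, 2:1, drop = FALSE]))
    }
  }

  structure(
    list(positions = positions, resolution = resolution, type = type,
         charge = charge, mass = mass, chain = chain, resid = resid,
         resname = resname, box = box, exclusions = exclusions),
    class = "particle_system")
}

#' Number of particles in a system
#' @param x a `particle_system`.
#' @return Integer particle count.
#' @export
n_particles <- function(x) {
  stopifnot(inherits(x, "particle_system"))
  nrow(x$positions)
}

#' @export
print.particle_system <- function(x, ...) {
  n <- n_particles(x)
  cat(sprintf("particle_system: %d particles (%d UA, %d CG), %d chain(s)%s\n",
              n, sum(x$resolution == "UA"), sum(x$resolution == "CG"),
              length(unique(x$chain)),
              if (is.null(x$box)) ", non-periodic"
              else sprintf(", box %.3f x %.3f x %.3f nm", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Minimum-image displacement vectors
#'
#' Applies the minimum-image convention componentwise for an orthorhombic box;
#' passes displacements through unchanged when `box` is `NULL`.
#'
#' @param d numeric matrix (n x 3) or length-3 vector of displacements (nm).
#' @param box length-3 box edge lengths in nm, or `NULL`.
#' @return Displacements wrapped into `[-L/2, L/2)` per component.
#' @export
minimum_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  } else {
    d <- d - box * round(d / box)
  }
  d
}

#' Mass-weighted center of mass
#' @param positions n x 3 coordinate matrix (nm).
#' @param masses particle masses (amu).
#' @return Length-3 center-of-mass vector.
#' @export
center_of_mass <- function(positions, masses = NULL) {
  positions <- as.matrix(positions)
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  colSums(positions * masses) / sum(masses)
}
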