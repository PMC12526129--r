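#' Physical constants (GROMACS unit system)
#'
#' Boltzmann constant in kJ/mol/K and the Coulomb prefactor
#' \eqn{1/(4\pi\epsilon_0)} in kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}.
#' @name constants
#' @keywords internal
NULL

KB_KJMOL <- 0.0083144621
COULOMB_KJMOL <- 138.935458

#' Build a hybrid pair-parameter table
#'
#' Stores Lennard-Jones cross terms per ordered type pair with symmetric
#' lookup, per-type charge defaults, the two global well-depth scaling factors
#' (`eps_cg` for CG-CG pairs, `eps_dual` for UA-CG pairs), and the
#' electrostatics settings (relative dielectric inside the cutoff and the
#' reaction-field dielectric beyond it).
#'
#' The scaling factors multiply well depths only: `eps_cg` rescales every CG-CG
#' Lennard-Jones epsilon and `eps_dual` every mixed-resolution epsilon, while
#' sigma and all UA-UA terms are untouched. An optional switch extends the
#' scaling to Coulomb energies of the same pair classes.
#'
#' @param pairs data frame with columns `type_i`, `type_j`, `epsilon`
#'   (kJ/mol, >= 0) and `sigma` (nm, > 0). Either order of a pair may be given;
#'   lookup is symmetric.
#' @param charges optional named numeric vector of per-type default charges (e).
#' @param eps_cg scaling factor applied to CG-CG well depths; default 0.2.
#' @param eps_dual scaling factor applied to UA-CG well depths; default 0.8.
#' @param dielectric relative dielectric constant inside the cutoff.
#' @param rf_dielectric reaction-field dielectric beyond the cutoff
#'   (`Inf` = conducting boundary).
#' @param cutoff nonbonded cutoff in nm (default 1.2).
#' @param scale_coulomb logical; also scale Coulomb energies of CG-CG and UA-CG
#'   pairs by `eps_cg` / `eps_dual`. Off by default: the calibration literature
#'   rescales Lennard-Jones well depths and leaves the dielectric model alone.
#' @param aliases optional named character vector mapping an alias type label
#'   to the type whose parameters it borrows (e.g. a coil backbone bead reusing
#'   the Asn side-chain bead parameters).
#'
#' @return An object of class `pair_table`.
#' @export
pair_table <- function(pairs, charges = NULL,
                       eps_cg = 0.2, eps_dual = 0.8,
                       dielectric = 1, rf_dielectric = Inf,
                       cutoff = 1.2, scale_coulomb = FALSE,
                       aliases = NULL) {
  pairs <- as.data.frame(pairs)
  need <- c("type_i", "type_j", "epsilon", "sigma")
  if (!all(need %in% names(pairs)))
    stop("`pairs` needs columns type_i, type_j, epsilon, sigma")
  if (any(pairs$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(pairs$sigma <= 0)) stop("sigma must be > 0")
  for (f in c(eps_cg, eps_dual))
    if (!is.finite(f) || f <= 0 || f > 2)
      stop("scaling factors must lie in (0, 2]")

  key <- pair_key(pairs$type_i, pairs$type_j)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    rows <- which(key == dup)
    same <- length(unique(pairs$epsilon[rows])) == 1L &&
      length(unique(pairs$sigma[rows])) == 1L
    if (!same)
      stop(sprintf("conflicting duplicate pair rows for %s (rows %s)",
                   dup, paste(rows, collapse = ", ")))
    keep <- !duplicated(key)
    pairs <- pairs[keep, , drop = FALSE]
    key <- key[keep]
  }

  eps <- pairs$epsilon; names(eps) <- key
  sig <- pairs$sigma;   names(sig) <- key

  if (!is.null(charges) && is.null(names(charges)))
    stop("`charges` must be a named vector (type -> charge)")

  if (!is.null(aliases) && is.null(names(aliases)))
    stop("`aliases` must be a named vector (alias -> existing type)")

  structure(
    list(epsilon = eps, sigma = sig, charges = charges,
         eps_cg = eps_cg, eps_dual = eps_dual,
         dielectric = dielectric, rf_dielectric = rf_dielectric,
         cutoff = cutoff, scale_coulomb = scale_coulomb,
         aliases = aliases),
    class = "pair_table")
}

resolve_alias <- function(table, type) {
  if (is.null(table$aliases)) return(type)
  hit <- type %in% names(table$aliases)
  type[hit] <- unname(table$aliases[type[hit]])
  type
}

pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Look up Lennard-Jones parameters for a type pair
#'
#' Lookup is symmetric in the two labels. Unknown pairs raise an error naming
#' the offending pair.
#'
#' @param table a `pair_table`.
#' @param type_i,type_j particle type labels (vectors recycle together).
#' @return A list with numeric vectors `epsilon` (kJ/mol) and `sigma` (nm).
#' @export
lookup_pair <- function(table, type_i, type_j) {
  key <- pair_key(resolve_alias(table, as.character(type_i)),
                  resolve_alias(table, as.character(type_j)))
  eps <- table$epsilon[key]
  if (anyNA(eps)) {
    miss <- key[which(is.na(eps))[1]]
    stop(sprintf("no pair parameters for type pair %s",
                 gsub("\\|", " - ", miss)))
  }
  list(epsilon = unname(eps), sigma = unname(table$sigma[key]))
}

#' Lorentz-Berthelot combining rule
#'
#' Geometric mean for the well depth, arithmetic mean for the size parameter:
#' the baseline that pair-specific fitting overrides.
#'
#' @param eps_i,eps_j well depths (kJ/mol, >= 0).
#' @param sigma_i,sigma_j size parameters (nm, > 0).
#' @return List with `epsilon` and `sigma` of the combined pair.
#' @export
combine_lorentz_berthelot <- function(eps_i, sigma_i, eps_j, sigma_j) {
  if (any(eps_i < 0) || any(eps_j < 0)) stop("epsilon must be non-negative")
  if (any(sigma_i <= 0) || any(sigma_j <= 0)) stop("sigma must be positive")
  list(epsilon = sqrt(eps_i * eps_j), sigma = (sigma_i + sigma_j) / 2)
}

#' Effective (scaled) pair parameters for a pair class
#'
#' Applies the table's scaling layer for the resolution class of a pair:
#' CG-CG well depths are multiplied by `eps_cg`, UA-CG well depths by
#' `eps_dual`, UA-UA terms pass through unchanged. Sigma is never modified.
#'
#' @param table a `pair_table`.
#' @param res_i,res_j resolution tags (`"UA"`/`"CG"`), vectors recycle.
#' @return Numeric vector of multiplicative factors on the stored epsilon.
#' @export
scaling_factor <- function(table, res_i, res_j) {
  both_cg <- res_i == "CG" & res_j == "CG"
  mixed <- res_i != res_j
  out <- rep(1, length(both_cg))
  out[both_cg] <- table$eps_cg
  out[mixed] <- table$eps_dual
  out
}

#' Apply the scaling layer to the whole stored table
#'
#' Expands the stored per-pair parameters into the three effective parameter
#' sets actually used by the energy model (UA-UA unscaled, CG-CG scaled by
#' `eps_cg`, UA-CG scaled by `eps_dual`).
#'
#' @param table a `pair_table`.
#' @return A data frame with one row per stored pair and columns
#'   `type_i`, `type_j`, `sigma`, `epsilon_ua_ua`, `epsilon_cg_cg`,
#'   `epsilon_ua_cg`.
#' @export
apply_scaling <- function(table) {
  key <- names(table$epsilon)
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(
    type_i = vapply(parts, `[[`, "", 1L),
    type_j = vapply(parts, `[[`, "", 2L),
    sigma = unname(table$sigma),
    epsilon_ua_ua = unname(table$epsilon),
    epsilon_cg_cg = unname(table$epsilon) * table$eps_cg,
    epsilon_ua_cg = unname(table$epsilon) * table$eps_dual,
    row.names = NULL)
}
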