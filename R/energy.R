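#' Lennard-Jones 12-6 pair energy
#'
#' Standard 12-6 form \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]}. With
#' `shift = TRUE` the potential is shifted so it vanishes at `cutoff`
#' (energies are then continuous across the cutoff, which keeps toy dynamics
#' well behaved).
#'
#' @param r pair separation in nm (vectorized, > 0).
#' @param epsilon well depth in kJ/mol (>= 0).
#' @param sigma zero-crossing distance in nm (> 0).
#' @param shift logical; subtract the value at `cutoff`.
#' @param cutoff cutoff in nm, used only when `shift = TRUE`.
#' @return Energy in kJ/mol.
#' @export
lj_energy <- function(r, epsilon, sigma, shift = FALSE, cutoff = 1.2) {
  if (any(r <= 0)) stop("pair distance r must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  sr6 <- (sigma / r)^6
  u <- 4 * epsilon * (sr6^2 - sr6)
  if (shift) {
    sc6 <- (sigma / cutoff)^6
    u <- u - 4 * epsilon * (sc6^2 - sc6)
  }
  u
}

#' Derivative of the (optionally shifted) Lennard-Jones energy
#' @inheritParams lj_energy
#' @return dU/dr in kJ/mol/nm (the shift does not affect the derivative).
#' @keywords internal
lj_dudr <- function(r, epsilon, sigma) {
  sr6 <- (sigma / r)^6
  -24 * epsilon / r * (2 * sr6^2 - sr6)
}

reaction_field_consts <- function(cutoff, dielectric, rf_dielectric) {
  krf <- if (is.infinite(rf_dielectric)) {
    1 / (2 * cutoff^3)
  } else {
    (rf_dielectric - dielectric) / (cutoff^3 * (2 * rf_dielectric + dielectric))
  }
  list(krf = krf, crf = 1 / cutoff + krf * cutoff^2)
}

#' Reaction-field Coulomb pair energy
#'
#' Cutoff electrostatics with the dielectric response beyond the cutoff folded
#' into a quadratic reaction-field term:
#' \deqn{U(r) = \frac{f q_1 q_2}{\epsilon_r}\left(\frac 1r + k_{rf} r^2 - c_{rf}\right)}
#' with \eqn{k_{rf}} set by the reaction-field dielectric
#' (\eqn{1/(2 r_c^3)} for a conducting boundary) and \eqn{c_{rf}} chosen so the
#' energy is exactly zero at the cutoff. Beyond the cutoff the energy is zero
#' by contract.
#'
#' @param r separation in nm (vectorized, > 0).
#' @param q1,q2 charges in elementary units.
#' @param cutoff cutoff radius in nm.
#' @param dielectric relative dielectric constant inside the cutoff.
#' @param rf_dielectric dielectric beyond the cutoff; `Inf` (default) is the
#'   conducting-boundary limit.
#' @return Energy in kJ/mol.
#' @export
coulomb_reaction_field <- function(r, q1, q2, cutoff = 1.2, dielectric = 1,
                                   rf_dielectric = Inf) {
  if (any(r <= 0)) stop("pair distance r must be positive")
  rf <- reaction_field_consts(cutoff, dielectric, rf_dielectric)
  u <- (COULOMB_KJMOL / dielectric) * q1 * q2 * (1 / r + rf$krf * r^2 - rf$crf)
  u[r > cutoff] <- 0
  u
}

coulomb_rf_dudr <- function(r, q1, q2, cutoff, dielectric, rf_dielectric) {
  rf <- reaction_field_consts(cutoff, dielectric, rf_dielectric)
  du <- (COULOMB_KJMOL / dielectric) * q1 * q2 * (-1 / r^2 + 2 * rf$krf * r)
  du[r > cutoff] <- 0
  du
}

# Enumerate non-excluded i<j pairs within the cutoff; returns pairwise
# geometry plus per-pair parameters with the resolution-class scaling applied.
pair_list <- function(system, table) {
  n <- n_particles(system)
  if (n < 2L)
    return(NULL)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 2L]; j <- idx[, 1L]  # upper.tri(arr.ind) gives row<col as (row=j, col=i)
  # drop exclusions
  if (nrow(system$exclusions) > 0L) {
    ex <- paste(pmin(system$exclusions[, 1], system$exclusions[, 2]),
                pmax(system$exclusions[, 1], system$exclusions[, 2]))
    keep <- !(paste(pmin(i, j), pmax(i, j)) %in% ex)
    i <- i[keep]; j <- j[keep]
  }
  if (length(i) == 0L) return(NULL)
  d <- minimum_image(system$positions[i, , drop = FALSE] -
                       system$positions[j, , drop = FALSE], system$box)
  r <- sqrt(rowSums(d^2))
  within <- r <= table$cutoff
  i <- i[within]; j <- j[within]; d <- d[within, , drop = FALSE]; r <- r[within]
  if (length(i) == 0L) return(NULL)
  p <- lookup_pair(table, system$type[i], system$type[j])
  fac <- scaling_factor(table, system$resolution[i], system$resolution[j])
  qfac <- if (isTRUE(table$scale_coulomb)) fac else rep(1, length(i))
  cls <- ifelse(system$resolution[i] == system$resolution[j],
                ifelse(system$resolution[i] == "UA", "UA", "CG"), "UA-CG")
  list(i = i, j = j, d = d, r = r,
       epsilon = p$epsilon * fac, sigma = p$sigma,
       qq = system$charge[i] * system$charge[j] * qfac,
       class = cls)
}

#' Hybrid-model energy with three-way resolution decomposition
#'
#' Sums shifted Lennard-Jones and reaction-field Coulomb energies over all
#' non-excluded particle pairs within the cutoff (minimum image when the
#' system carries a box), routing each pair by its two resolution tags into
#' \eqn{U_{UA}}, \eqn{U_{CG}}, or \eqn{U_{UA-CG}} so that
#' \eqn{U_{total} = U_{UA} + U_{CG} + U_{UA-CG}} holds exactly. The scaling
#' layer (`eps_cg` on CG-CG, `eps_dual` on UA-CG well depths) is applied
#' inside the sum.
#'
#' @param system a `particle_system`.
#' @param table a `pair_table`; every type label in `system` must resolve.
#' @param shift_lj logical; shift the LJ term to zero at the cutoff
#'   (default `TRUE`).
#' @return An object of class `energy_decomposition`: a list with `U_UA`,
#'   `U_CG`, `U_UA_CG`, `U_total` and per-class `lj` / `coulomb` sub-totals
#'   (all kJ/mol).
#' @export
energy_decomposition <- function(system, table, shift_lj = TRUE) {
  zero <- c(UA = 0, CG = 0, `UA-CG` = 0)
  lj <- coul <- zero
  pl <- pair_list(system, table)
  if (!is.null(pl)) {
    ulj <- lj_energy(pl$r, pl$epsilon, pl$sigma,
                     shift = shift_lj, cutoff = table$cutoff)
    ucl <- {
      rf <- reaction_field_consts(table$cutoff, table$dielectric,
                                  table$rf_dielectric)
      (COULOMB_KJMOL / table$dielectric) * pl$qq *
        (1 / pl$r + rf$krf * pl$r^2 - rf$crf)
    }
    for (cl in names(zero)) {
      sel <- pl$class == cl
      lj[cl] <- sum(ulj[sel])
      coul[cl] <- sum(ucl[sel])
    }
  }
  tot <- lj + coul
  structure(
    list(U_UA = unname(tot["UA"]), U_CG = unname(tot["CG"]),
         U_UA_CG = unname(tot["UA-CG"]),
         U_total = unname(tot["UA"] + tot["CG"] + tot["UA-CG"]),
         lj = lj, coulomb = coul),
    class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("U_total = %.6g kJ/mol (UA %.6g, CG %.6g, UA-CG %.6g)\n",
              x$U_total, x$U_UA, x$U_CG, x$U_UA_CG))
  invisible(x)
}

#' Total potential energy of a system under the hybrid model
#' @inheritParams energy_decomposition
#' @return Scalar energy in kJ/mol.
#' @export
potential_energy <- function(system, table, shift_lj = TRUE) {
  energy_decomposition(system, table, shift_lj = shift_lj)$U_total
}

#' Forces on all particles under the hybrid model
#'
#' Analytic negative gradient of the shifted-LJ + reaction-field energy used
#' by [energy_decomposition()] (the shift does not alter forces).
#'
#' @inheritParams energy_decomposition
#' @return n x 3 matrix of forces in kJ/mol/nm.
#' @export
compute_forces <- function(system, table) {
  n <- n_particles(system)
  f <- matrix(0, n, 3L)
  pl <- pair_list(system, table)
  if (is.null(pl)) return(f)
  dudr <- lj_dudr(pl$r, pl$epsilon, pl$sigma) +
    coulomb_rf_dudr(pl$r, 1, 1, table$cutoff, table$dielectric,
                    table$rf_dielectric) * pl$qq
  # force on i along +d (d = x_i - x_j): F_i = -dU/dr * d/r, F_j = -F_i
  fx <- pl$d * (-dudr / pl$r)
  acc_i <- rowsum(fx, group = pl$i)
  acc_j <- rowsum(fx, group = pl$j)
  f[as.integer(rownames(acc_i)), ] <- f[as.integer(rownames(acc_i)), ] + acc_i
  f[as.integer(rownames(acc_j)), ] <- f[as.integer(rownames(acc_j)), ] - acc_j
  f
}
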