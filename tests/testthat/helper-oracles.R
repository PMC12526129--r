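# Independent reference implementations used to cross-check the package:
# a naive O(N^2) energy double loop, an all-27-images periodic energy, and a
# union-find single-linkage clusterer. These are deliberately written in the
# most literal style possible and share no code with the package internals.

KB_REF <- 0.0083144621
COULOMB_REF <- 138.935458

# naive double-loop hybrid energy with explicit per-class accumulators
brute_force_energy <- function(system, table, shift_lj = TRUE) {
  n <- nrow(system$positions)
  acc <- c(UA = 0, CG = 0, `UA-CG` = 0)
  excl <- system$exclusions
  is_excluded <- function(i, j) {
    nrow(excl) > 0 && any(excl[, 1] == i & excl[, 2] == j)
  }
  krf <- if (is.infinite(table$rf_dielectric)) 1 / (2 * table$cutoff^3) else
    (table$rf_dielectric - table$dielectric) /
      (table$cutoff^3 * (2 * table$rf_dielectric + table$dielectric))
  crf <- 1 / table$cutoff + krf * table$cutoff^2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (is_excluded(i, j)) next
      d <- system$positions[i, ] - system$positions[j, ]
      if (!is.null(system$box))
        d <- d - system$box * round(d / system$box)
      r <- sqrt(sum(d^2))
      if (r > table$cutoff) next
      p <- lookup_pair(table, system$type[i], system$type[j])
      ri <- system$resolution[i]; rj <- system$resolution[j]
      cls <- if (ri == rj && ri == "UA") "UA"
             else if (ri == rj) "CG" else "UA-CG"
      fac <- if (cls == "CG") table$eps_cg else if (cls == "UA-CG") table$eps_dual else 1
      eps <- p$epsilon * fac
      sr6 <- (p$sigma / r)^6
      u <- 4 * eps * (sr6^2 - sr6)
      if (shift_lj) {
        sc6 <- (p$sigma / table$cutoff)^6
        u <- u - 4 * eps * (sc6^2 - sc6)
      }
      qq <- system$charge[i] * system$charge[j]
      if (isTRUE(table$scale_coulomb)) qq <- qq * fac
      u <- u + (COULOMB_REF / table$dielectric) * qq * (1 / r + krf * r^2 - crf)
      acc[cls] <- acc[cls] + u
    }
  }
  list(U_UA = unname(acc["UA"]), U_CG = unname(acc["CG"]),
       U_UA_CG = unname(acc["UA-CG"]), U_total = sum(acc))
}

# periodic pair energy where each pair distance is minimized over all 27
# neighbor images explicitly, instead of the componentwise minimum-image trick
image_oracle_energy <- function(system, table, shift_lj = TRUE) {
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  n <- nrow(system$positions)
  tot <- 0
  krf <- 1 / (2 * table$cutoff^3)
  crf <- 1 / table$cutoff + krf * table$cutoff^2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d0 <- system$positions[i, ] - system$positions[j, ]
      imgs <- sweep(shifts %*% diag(system$box), 2, d0, function(s, d) d + s)
      r <- min(sqrt(rowSums(imgs^2)))
      if (r > table$cutoff) next
      p <- lookup_pair(table, system$type[i], system$type[j])
      fac <- if (system$resolution[i] == system$resolution[j]) {
        if (system$resolution[i] == "CG") table$eps_cg else 1
      } else table$eps_dual
      eps <- p$epsilon * fac
      sr6 <- (p$sigma / r)^6
      u <- 4 * eps * (sr6^2 - sr6)
      if (shift_lj) {
        sc6 <- (p$sigma / table$cutoff)^6
        u <- u - 4 * eps * (sc6^2 - sc6)
      }
      qq <- system$charge[i] * system$charge[j]
      tot <- tot + u + (COULOMB_REF / table$dielectric) * qq *
        (1 / r + krf * r^2 - crf)
    }
  }
  tot
}

# single-linkage chain clustering by union-find, no graph library
union_find_clusters <- function(system, cutoff) {
  ids <- unique(system$chain)
  parent <- seq_along(ids)
  find <- function(k) {
    while (parent[k] != k) k <- parent[k]
    k
  }
  n <- nrow(system$positions)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (system$chain[i] == system$chain[j]) next
      d <- system$positions[i, ] - system$positions[j, ]
      if (!is.null(system$box))
        d <- d - system$box * round(d / system$box)
      if (sum(d^2) < cutoff^2) {
        ra <- find(match(system$chain[i], ids))
        rb <- find(match(system$chain[j], ids))
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(ids), find, 0L)
  unname(lapply(split(ids, roots), unname))
}

# partition equality irrespective of cluster and member order
same_partition <- function(a, b) {
  norm <- function(p) sort(vapply(p, function(x) paste(sort(x), collapse = ","), ""))
  identical(norm(a), norm(b))
}

# a reproducible multi-chain boxed system for clustering tests
random_chain_system <- function(n_chains, beads_per_chain = 3, box = c(4, 4, 4),
                                spread = 0.25, seed = 1) {
  set.seed(seed)
  centers <- cbind(runif(n_chains, 0, box[1]), runif(n_chains, 0, box[2]),
                   runif(n_chains, 0, box[3]))
  pos <- NULL; chain <- character(0)
  for (c_i in seq_len(n_chains)) {
    pos <- rbind(pos, sweep(matrix(rnorm(beads_per_chain * 3, 0, spread),
                                   beads_per_chain, 3), 2, centers[c_i, ], `+`))
    chain <- c(chain, rep(sprintf("c%02d", c_i), beads_per_chain))
  }
  pos <- pos %% matrix(box, nrow(pos), 3, byrow = TRUE)
  particle_system(pos, resolution = "UA", type = "X", chain = chain, box = box)
}

# a reproducible random mixed-resolution boxed system for energy tests
random_mixed_system <- function(n, seed, box = c(2.5, 2.5, 2.5),
                                charged = TRUE) {
  set.seed(seed)
  # jittered grid placement keeps pair distances away from the LJ core
  g <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(g), y = seq_len(g), z = seq_len(g)))
  grid <- grid[seq_len(n), , drop = FALSE] * (box[1] / (g + 1))
  pos <- grid + matrix(runif(3 * n, -0.08, 0.08), n, 3)
  particle_system(
    pos %% matrix(box, n, 3, byrow = TRUE),
    resolution = sample(c("UA", "CG"), n, replace = TRUE),
    type = sample(c("LEU", "SER", "PHE"), n, replace = TRUE),
    charge = if (charged) sample(c(-1, 0, 0, 1), n, replace = TRUE) else 0,
    mass = 72, box = box)
}

random_mixed_table <- function(...) {
  types <- c("LEU", "SER", "PHE")
  grid <- expand.grid(i = types, j = types, stringsAsFactors = FALSE)
  grid <- grid[grid$i <= grid$j, ]
  base_eps <- c(LEU = 4.5, SER = 2.5, PHE = 4.8)
  base_sig <- c(LEU = 0.49, SER = 0.42, PHE = 0.52)
  comb <- combine_lorentz_berthelot(base_eps[grid$i], base_sig[grid$i],
                                    base_eps[grid$j], base_sig[grid$j])
  pair_table(data.frame(type_i = grid$i, type_j = grid$j,
                        epsilon = unname(comb$epsilon),
                        sigma = unname(comb$sigma)), ...)
}
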