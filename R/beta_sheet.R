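# Geometric beta-strand detection and amyloid registry classification.
#
# Chains are represented by one backbone (C-alpha) site per residue; the
# criteria are purely geometric so they work for mixed-resolution chains
# where hydrogen-bond-based secondary-structure assignment is undefined.

# ordered C-alpha coordinates and residue ids for one chain
chain_backbone <- function(system, chain, ca_types = NULL) {
  sel <- which(system$chain == chain)
  if (!is.null(ca_types)) sel <- sel[system$type[sel] %in% ca_types]
  sel <- sel[order(system$resid[sel])]
  list(idx = sel, resid = system$resid[sel],
       resname = system$resname[sel],
       pos = system$positions[sel, , drop = FALSE])
}

#' Detect beta-strand segments in a frame
#'
#' A residue is "extended" when the distance between the C-alpha sites of its
#' two sequence neighbors exceeds `ext_min` (a pseudo-extension criterion;
#' terminal residues inherit the flag of their single interior neighbor). An
#' extended run becomes a strand only when it is paired: at least `min_len`
#' consecutive residues each have a cross-chain C-alpha partner at a distance
#' inside `pair_range` on a common partner chain. Isolated extended chains
#' are therefore never reported.
#'
#' @param system a `particle_system` with one backbone site per residue.
#' @param chains chain ids to analyze (default all).
#' @param ext_min pseudo-extension threshold in nm (default 0.64).
#' @param pair_range allowed cross-strand C-alpha pairing distance in nm
#'   (default `c(0.42, 0.58)`, bracketing the canonical ~0.48 nm sheet
#'   spacing).
#' @param min_len minimum paired run length in residues (default 3).
#' @param ca_types optional particle type labels identifying backbone sites.
#' @return Data frame with one row per strand segment: `chain`, `res_start`,
#'   `res_end`, `partner` (chain id), `length`.
#' @export
detect_beta_strands <- function(system, chains = NULL, ext_min = 0.64,
                                pair_range = c(0.42, 0.58), min_len = 3L,
                                ca_types = NULL) {
  ids <- unique(system$chain)
  if (!is.null(chains)) ids <- ids[ids %in% chains]
  bb <- lapply(ids, chain_backbone, system = system, ca_types = ca_types)
  names(bb) <- ids
  usable <- vapply(bb, function(b) length(b$idx) >= 3L, TRUE)
  if (any(!usable))
    warning(sprintf("skipping chain(s) without enough backbone sites: %s",
                    paste(ids[!usable], collapse = ", ")))
  ids <- ids[usable]; bb <- bb[usable]

  extended <- lapply(bb, function(b) {
    n <- nrow(b$pos)
    ext <- rep(FALSE, n)
    if (n >= 3L) {
      d <- sqrt(rowSums((b$pos[3:n, , drop = FALSE] -
                           b$pos[1:(n - 2), , drop = FALSE])^2))
      ext[2:(n - 1)] <- d > ext_min
      ext[1] <- ext[2]; ext[n] <- ext[n - 1]
    }
    ext
  })

  out <- list(); oi <- 0L
  for (a in seq_along(ids)) {
    ba <- bb[[a]]; exa <- extended[[a]]
    if (!any(exa)) next
    for (b2 in seq_along(ids)) {
      if (b2 == a) next
      bbv <- bb[[b2]]; exb <- extended[[b2]]
      if (!any(exb)) next
      # per-residue pairing: nearest extended C-alpha on the partner chain
      paired <- rep(FALSE, length(exa))
      pb <- bbv$pos[exb, , drop = FALSE]
      if (nrow(pb) == 0L) next
      for (i in which(exa)) {
        dmin <- sqrt(min(rowSums(sweep(pb, 2, ba$pos[i, ])^2)))
        paired[i] <- dmin >= pair_range[1] && dmin <= pair_range[2]
      }
      r <- rle(paired)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_len)) {
        oi <- oi + 1L
        out[[oi]] <- data.frame(
          chain = ids[a],
          res_start = ba$resid[starts[k]], res_end = ba$resid[ends[k]],
          partner = ids[b2], length = r$lengths[k])
      }
    }
  }
  if (oi == 0L)
    return(data.frame(chain = character(0), res_start = integer(0),
                      res_end = integer(0), partner = character(0),
                      length = integer(0)))
  do.call(rbind, out)
}

# in-register templates over the four-residue amyloidogenic core:
# parallel pairs identical positions (1-1 ... 4-4), antiparallel reversed
REGISTRY_PARALLEL <- c(`1` = 1L, `2` = 2L, `3` = 3L, `4` = 4L)
REGISTRY_ANTIPARALLEL <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)

#' Classify the registry of a strand pair
#'
#' Orientation comes from the sign of the dot product of the two strand
#' direction vectors (first-to-last C-alpha); near-perpendicular pairs
#' (|cos| < `cos_min`) are labeled `other`. The residue pairing map assigns
#' each core residue (positions 1-4, the L-V-F-F stretch) its nearest
#' cross-strand C-alpha. The pair is in register iff the map matches the
#' parallel template (1-1, 2-2, 3-3, 4-4) or the antiparallel template
#' (1-4, 2-3, 3-2, 4-1) exactly, and only in-register pairs receive an
#' amyloid label. Classification is symmetric in the two chains.
#'
#' @param system a `particle_system`.
#' @param chain_a,chain_b the two strand chain ids.
#' @param core_resids residue indices of the amyloidogenic core (default 1:4).
#' @param cos_min orientation decisiveness threshold on |cos| (default 0.3).
#' @param ca_types optional backbone type labels.
#' @return Object of class `registry_assignment`: `orientation`
#'   (`"parallel"` / `"antiparallel"` / `"other"`), `in_register`, `pairing`
#'   (named integer map), `label` (`"parallel-amyloid"`,
#'   `"antiparallel-amyloid"`, `"other"`, or `"unclassifiable"`).
#' @export
classify_registry <- function(system, chain_a, chain_b, core_resids = 1:4,
                              cos_min = 0.3, ca_types = NULL) {
  a <- chain_backbone(system, chain_a, ca_types)
  b <- chain_backbone(system, chain_b, ca_types)
  ka <- match(core_resids, a$resid)
  kb <- match(core_resids, b$resid)
  if (sum(!is.na(ka)) < 3L || sum(!is.na(kb)) < 3L)
    return(structure(list(orientation = "other", in_register = FALSE,
                          pairing = NULL, label = "unclassifiable"),
                     class = "registry_assignment"))
  va <- a$pos[nrow(a$pos), ] - a$pos[1, ]
  vb <- b$pos[nrow(b$pos), ] - b$pos[1, ]
  cosang <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  orientation <- if (abs(cosang) < cos_min) "other"
                 else if (cosang > 0) "parallel" else "antiparallel"

  pairing <- vapply(core_resids, function(res) {
    i <- match(res, a$resid)
    if (is.na(i)) return(NA_integer_)
    d2 <- rowSums(sweep(b$pos, 2, a$pos[i, ])^2)
    b$resid[which.min(d2)]
  }, integer(1))
  names(pairing) <- core_resids

  in_register <- FALSE
  if (orientation == "parallel") {
    in_register <- !anyNA(pairing) &&
      all(pairing == REGISTRY_PARALLEL[as.character(core_resids)])
  } else if (orientation == "antiparallel") {
    in_register <- !anyNA(pairing) &&
      all(pairing == REGISTRY_ANTIPARALLEL[as.character(core_resids)])
  }
  label <- if (orientation == "parallel" && in_register) "parallel-amyloid"
           else if (orientation == "antiparallel" && in_register) "antiparallel-amyloid"
           else "other"
  structure(list(orientation = orientation, in_register = in_register,
                 pairing = pairing, label = label),
            class = "registry_assignment")
}

#' @export
print.registry_assignment <- function(x, ...) {
  cat(sprintf("registry_assignment: %s (%s%s)\n", x$label, x$orientation,
              if (x$in_register) ", in register" else ""))
  invisible(x)
}

#' Beta-sheet and amyloid fractions over analyzed frames
#'
#' Aggregates strand-pair registry labels and residue counts into the four
#' summary fractions: the beta fraction (residues in strands over residues in
#' the cluster), the amyloid fraction (in-register pairs over classified
#' pairs), and its parallel/antiparallel split. Frames are weighted by
#' cluster size (residue count) for the beta fraction and by classified-pair
#' count for the registry fractions, so permuting frame order changes
#' nothing.
#'
#' @param pair_labels character vector of registry labels pooled over frames
#'   (or a list of per-frame vectors).
#' @param strand_residues residues participating in strands, per frame or
#'   pooled (numeric).
#' @param cluster_residues residues in the analyzed cluster(s), matching
#'   `strand_residues`.
#' @return List with `beta`, `amyloid`, `parallel`, `antiparallel` fractions
#'   and logical `no_strands` flag (fractions are 0, not NA, when no strands
#'   exist).
#' @export
amyloid_fractions <- function(pair_labels, strand_residues = 0,
                              cluster_residues = 0) {
  if (is.list(pair_labels)) pair_labels <- unlist(pair_labels, use.names = FALSE)
  pair_labels <- pair_labels[pair_labels != "unclassifiable"]
  n_pairs <- length(pair_labels)
  n_par <- sum(pair_labels == "parallel-amyloid")
  n_anti <- sum(pair_labels == "antiparallel-amyloid")
  sr <- sum(strand_residues); cr <- sum(cluster_residues)
  no_strands <- sr == 0
  list(
    beta = if (cr > 0) sr / cr else 0,
    amyloid = if (n_pairs > 0) (n_par + n_anti) / n_pairs else 0,
    parallel = if (n_pairs > 0) n_par / n_pairs else 0,
    antiparallel = if (n_pairs > 0) n_anti / n_pairs else 0,
    no_strands = no_strands)
}
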