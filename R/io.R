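# Readers and writers for the on-disk formats: GRO / PDB / XYZ coordinates,
# whitespace-delimited pair-parameter files, umbrella-window series, PMF
# tables, and the flat key-value run configuration.
#
# Internal units are nm / kJ/mol / e / amu / ps everywhere; unit conversion
# happens only here (PDB and XYZ carry Angstrom on disk, GRO carries nm).

guess_format <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  switch(tolower(tools::file_ext(path)),
         gro = "gro", pdb = "pdb", xyz = "xyz",
         stop(sprintf("cannot guess coordinate format of '%s'; pass `format`",
                      path)))
}

#' Read a coordinate file into a particle system
#'
#' Supports GRO (nm, with box vectors), PDB (Angstrom, converted to nm), and
#' bare XYZ (Angstrom by convention, converted to nm). Resolution tags are
#' not part of any of these formats; supply them through `resolution_map`
#' (type label -> `"UA"`/`"CG"`), with unmapped types defaulting to
#' `default_resolution`.
#'
#' @param path file path.
#' @param format `"gro"`, `"pdb"`, or `"xyz"`; guessed from the extension
#'   when omitted.
#' @param resolution_map named character vector type -> resolution tag.
#' @param default_resolution tag for unmapped types (default `"UA"`).
#' @return A `particle_system` (no box for XYZ and box-less PDB files).
#' @export
read_coordinates <- function(path, format = NULL, resolution_map = NULL,
                             default_resolution = "UA") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- guess_format(path, format)
  parsed <- switch(format,
                   gro = read_gro(path),
                   pdb = read_pdb_file(path),
                   xyz = read_xyz(path),
                   stop(sprintf("unsupported format '%s'", format)))
  res <- rep(default_resolution, length(parsed$type))
  if (!is.null(resolution_map)) {
    hit <- parsed$type %in% names(resolution_map)
    res[hit] <- unname(resolution_map[parsed$type[hit]])
  }
  particle_system(parsed$positions, resolution = res, type = parsed$type,
                  chain = parsed$chain, resid = parsed$resid,
                  resname = parsed$resname, box = parsed$box)
}

read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop(sprintf("truncated GRO file (only %d lines)", length(lines)))
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count on line 2")
  if (length(lines) < 2L + n + 1L)
    stop(sprintf("truncated GRO file: expected %d atom lines, last good line is %d",
                 n, length(lines) - 2L))
  at <- lines[3:(2 + n)]
  num <- function(s, from, to) {
    v <- suppressWarnings(as.numeric(substr(s, from, to)))
    v
  }
  resid <- as.integer(num(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  type <- trimws(substr(at, 11, 15))
  x <- num(at, 21, 28); y <- num(at, 29, 36); z <- num(at, 37, 44)
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop(sprintf("malformed GRO atom record on line %d", 2L + bad[1]))
  bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]]))
  box <- if (length(bx) >= 3 && all(is.finite(bx[1:3])) && all(bx[1:3] > 0))
    bx[1:3] else NULL
  chain <- chain_from_resid(resid)
  list(positions = cbind(x, y, z), type = type, chain = chain,
       resid = resid, resname = resname, box = box)
}

read_pdb_file <- function(path) {
  lines <- readLines(path)
  at <- grep("^(ATOM  |HETATM)", lines)
  if (length(at) == 0L) stop("no ATOM records found")
  s <- lines[at]
  x <- suppressWarnings(as.numeric(substr(s, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(s, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(s, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0)
    stop(sprintf("malformed PDB coordinate record on line %d", at[bad[1]]))
  type <- trimws(substr(s, 13, 16))
  resname <- trimws(substr(s, 18, 20))
  chain <- substr(s, 22, 22)
  chain[chain == " "] <- "A"
  resid <- suppressWarnings(as.integer(substr(s, 23, 26)))
  box <- NULL
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 1L) {
    abc <- suppressWarnings(as.numeric(c(substr(cr, 7, 15), substr(cr, 16, 24),
                                         substr(cr, 25, 33))))
    if (all(is.finite(abc)) && all(abc > 0)) box <- abc / 10
  }
  list(positions = cbind(x, y, z) / 10, type = type, chain = chain,
       resid = resid, resname = resname, box = box)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("truncated XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ atom count on line 1")
  if (length(lines) < 2L + n)
    stop(sprintf("truncated XYZ file: expected %d atom lines, last good line is %d",
                 n, length(lines) - 2L))
  parts <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  bad <- which(lengths(parts) < 4L)
  if (length(bad) > 0)
    stop(sprintf("malformed XYZ record on line %d", 2L + bad[1]))
  type <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("non-numeric XYZ coordinates")
  list(positions = xyz / 10, type = type, chain = rep("A", n),
       resid = seq_len(n), resname = type, box = NULL)
}

chain_from_resid <- function(resid) {
  # GRO carries no chain field; start a new chain whenever resid decreases
  breaks <- c(TRUE, diff(resid) < 0)
  sprintf("C%d", cumsum(breaks))
}

#' Write a particle system to a coordinate file
#'
#' GRO preserves the box and nm coordinates to 0.001 nm; PDB and XYZ write
#' Angstrom. Chain identifiers wider than the format's field are truncated
#' (PDB) or dropped (GRO encodes chains only through residue numbering).
#'
#' @param system a `particle_system`.
#' @param path output path.
#' @param format `"gro"`, `"pdb"`, or `"xyz"` (guessed from the extension).
#' @param title title/comment line.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(system, path, format = NULL,
                              title = "hybridff system") {
  format <- guess_format(path, format)
  n <- n_particles(system)
  lines <- switch(format,
    gro = {
      at <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                    system$resid %% 100000L,
                    substr(ifelse(system$resname == "", "RES", system$resname), 1, 5),
                    substr(system$type, 1, 5), seq_len(n) %% 100000L,
                    system$positions[, 1], system$positions[, 2],
                    system$positions[, 3])
      bx <- if (is.null(system$box)) c(0, 0, 0) else system$box
      c(title, sprintf("%5d", n), at,
        sprintf("%10.5f%10.5f%10.5f", bx[1], bx[2], bx[3]))
    },
    pdb = {
      at <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                    seq_len(n) %% 100000L, substr(system$type, 1, 4),
                    substr(ifelse(system$resname == "", "RES", system$resname), 1, 3),
                    substr(system$chain, 1, 1), system$resid %% 10000L,
                    system$positions[, 1] * 10, system$positions[, 2] * 10,
                    system$positions[, 3] * 10)
      hdr <- if (!is.null(system$box))
        sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                system$box[1] * 10, system$box[2] * 10, system$box[3] * 10)
      else character(0)
      c(hdr, at, "END")
    },
    xyz = {
      c(sprintf("%d", n), title,
        sprintf("%-5s %12.6f %12.6f %12.6f", system$type,
                system$positions[, 1] * 10, system$positions[, 2] * 10,
                system$positions[, 3] * 10))
    },
    stop(sprintf("unsupported format '%s'", format)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a pair-parameter file
#'
#' Whitespace-delimited dialect: data rows `type_i type_j epsilon_kJmol
#' sigma_nm`, comment lines starting with `#`, alias rows
#' `alias NEW_TYPE EXISTING_TYPE` (the alias borrows the existing type's
#' parameters, e.g. a coil backbone bead reusing Asn side-chain bead
#' parameters), and settings rows `set key value` for the scalar
#' configuration (`eps_cg`, `eps_dual`, `dielectric`, `rf_dielectric`,
#' `cutoff`, `scale_coulomb`).
#'
#' @param path file path.
#' @return A `pair_table`.
#' @export
read_pair_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  rows <- list(); aliases <- character(0)
  settings <- list(eps_cg = 0.2, eps_dual = 0.8, dielectric = 1,
                   rf_dielectric = Inf, cutoff = 1.2, scale_coulomb = FALSE)
  seen <- list()  # pair key -> first line number, for duplicate reporting
  for (ln in keep) {
    p <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (p[1] == "alias") {
      if (length(p) != 3L) stop(sprintf("malformed alias row on line %d", ln))
      aliases[p[2]] <- p[3]
    } else if (p[1] == "set") {
      if (length(p) != 3L) stop(sprintf("malformed set row on line %d", ln))
      if (!p[2] %in% names(settings))
        stop(sprintf("unknown setting '%s' on line %d", p[2], ln))
      settings[[p[2]]] <- if (p[2] == "scale_coulomb") as.logical(p[3])
                          else as.numeric(p[3])
    } else {
      if (length(p) != 4L)
        stop(sprintf("malformed pair row on line %d (need 4 fields)", ln))
      eps <- as.numeric(p[3]); sig <- as.numeric(p[4])
      if (!is.finite(eps) || eps < 0)
        stop(sprintf("invalid epsilon on line %d (must be >= 0)", ln))
      if (!is.finite(sig) || sig <= 0)
        stop(sprintf("invalid sigma on line %d (must be > 0)", ln))
      key <- pair_key(p[1], p[2])
      if (!is.null(seen[[key]])) {
        prev <- seen[[key]]
        if (prev$epsilon != eps || prev$sigma != sig)
          stop(sprintf("conflicting duplicate pair rows for %s - %s on lines %d and %d",
                       p[1], p[2], prev$line, ln))
      } else {
        seen[[key]] <- list(epsilon = eps, sigma = sig, line = ln)
        rows[[length(rows) + 1L]] <- data.frame(
          type_i = p[1], type_j = p[2], epsilon = eps, sigma = sig)
      }
    }
  }
  if (length(rows) == 0L) stop("no pair rows found")
  pair_table(do.call(rbind, rows),
             eps_cg = settings$eps_cg, eps_dual = settings$eps_dual,
             dielectric = settings$dielectric,
             rf_dielectric = settings$rf_dielectric,
             cutoff = settings$cutoff, scale_coulomb = settings$scale_coulomb,
             aliases = if (length(aliases) > 0) aliases else NULL)
}

#' Write an umbrella window to a columnar text file
#'
#' Dialect: `#`-prefixed metadata block (`center_nm`, `k_kJmol_nm2`, `seed`,
#' `n_discarded`) followed by `step r_nm` columns.
#'
#' @param window an `umbrella_window`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_window <- function(window, path) {
  hdr <- c(sprintf("# center_nm %.10g", window$center),
           sprintf("# k_kJmol_nm2 %.10g", window$k),
           sprintf("# seed %d", window$seed),
           sprintf("# n_discarded %d", window$n_discarded))
  writeLines(c(hdr, sprintf("%d %.10g", seq_along(window$samples),
                            window$samples)), path)
  invisible(path)
}

#' Read an umbrella window file
#' @param path path written by [write_window()].
#' @return An `umbrella_window`.
#' @export
read_window <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getm <- function(key, default = NA) {
    hit <- grep(paste0("^# ", key, " "), meta, value = TRUE)
    if (length(hit) == 0L) return(default)
    as.numeric(sub(paste0("^# ", key, " "), "", hit[1]))
  }
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  samples <- vapply(strsplit(trimws(dat), "\\s+"),
                    function(p) as.numeric(p[2]), 0)
  umbrella_window(getm("center_nm"), getm("k_kJmol_nm2", 1000), samples,
                  n_discarded = getm("n_discarded", 0),
                  seed = getm("seed", NA))
}

#' Read all window files of an umbrella dataset directory
#' @param dir directory of `*.dat` window files.
#' @return List of `umbrella_window` objects.
#' @export
read_window_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.dat$", full.names = TRUE)
  if (length(files) == 0L) stop(sprintf("no window files (*.dat) in %s", dir))
  lapply(sort(files), read_window)
}

#' Write a PMF profile as columnar text
#' @param pmf a `pmf_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pmf <- function(pmf, path) {
  hdr <- c(sprintf("# temperature_K %g", pmf$temperature),
           sprintf("# zero %s", pmf$zero),
           "# r_nm F_kJmol counts")
  writeLines(c(hdr, sprintf("%.6f %.10g %g", pmf$r,
                            ifelse(is.finite(pmf$free_energy),
                                   pmf$free_energy, NA),
                            pmf$counts)), path)
  invisible(path)
}

#' Read a PMF profile written by [write_pmf()]
#' @param path file path.
#' @return A `pmf_profile`.
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  temp <- as.numeric(sub("^# temperature_K ", "",
                         grep("^# temperature_K", meta, value = TRUE)[1]))
  zero <- sub("^# zero ", "", grep("^# zero", meta, value = TRUE)[1])
  dat <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- t(vapply(strsplit(trimws(dat), "\\s+"), function(p) {
    v <- p[1:3]
    v[v == "NA"] <- NA_character_  # unpopulated bins; coerce silently
    as.numeric(v)
  }, numeric(3)))
  pmf_profile(m[, 1], m[, 2], temperature = temp, counts = m[, 3],
              zero = zero)
}

#' Read a flat key-value run configuration
#'
#' Dialect: one `key = value` per line, `#` comments. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path file path.
#' @param known character vector of permitted keys (default: the standard
#'   run-configuration keys).
#' @return Named list of values (numerics auto-converted).
#' @export
read_config <- function(path, known = c(
    "pair_table", "eps_cg", "eps_dual", "cutoff", "temperature", "friction",
    "timestep", "n_steps", "seed", "bias_k", "cluster_cutoff",
    "encounter_threshold", "fit_range_min", "fit_range_max", "out_dir",
    "log_level")) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- list()
  for (ln in keep) {
    p <- strsplit(lines[ln], "=", fixed = TRUE)[[1]]
    if (length(p) != 2L)
      stop(sprintf("malformed config line %d (need key = value)", ln))
    key <- trimws(p[1]); val <- trimws(p[2])
    if (!key %in% known)
      stop(sprintf("unknown config key '%s' on line %d", key, ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a resolved run configuration next to its outputs
#' @param config named list.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 12), "")),
             path)
  invisible(path)
}
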