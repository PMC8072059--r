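# File-format boundary: distances are nanometers in files and Angstrom in
# memory throughout the package.

#' Read a distance distribution file
#'
#' Whitespace-separated columns: distance axis (nm), density, and optional
#' lower/upper uncertainty bounds. Lines starting with `%` or `#` are
#' comments. Two-column files load with bands equal to the density.
#'
#' @param path File path.
#' @return A normalized `distance_distribution` (axis converted to
#'   Angstrom).
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[%#]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no data lines in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !ncol %in% c(2, 4)) {
    stop("expected 2 or 4 whitespace-separated columns in ", path)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = ncol, byrow = TRUE)
  if (any(is.na(m))) {
    stop("non-numeric value at line ",
         which(is.na(rowSums(m)))[1], " of ", path)
  }
  if (any(diff(m[, 1]) <= 0)) {
    stop("non-monotonic distance axis in ", path, " at line ",
         which(diff(m[, 1]) <= 0)[1] + 1)
  }
  if (any(m[, 2] < 0)) {
    stop("negative density in ", path, " at line ", which(m[, 2] < 0)[1])
  }
  r <- m[, 1] * 10
  if (ncol == 4) {
    distance_distribution(r, m[, 2], band_lo = m[, 3], band_hi = m[, 4])
  } else {
    distance_distribution(r, m[, 2], band_lo = m[, 2], band_hi = m[, 2])
  }
}

#' Write a distance distribution file
#'
#' Four columns: distance (nm), density, lower band, upper band. Missing
#' bands are written as copies of the density.
#'
#' @param dist A `distance_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "distance_distribution"))
  lo <- dist$band_lo %||% dist$p
  hi <- dist$band_hi %||% dist$p
  m <- cbind(dist$r_axis / 10, dist$p, lo, hi)
  writeLines(apply(m, 1, function(row) {
    paste(formatC(row, format = "e", digits = 8), collapse = " ")
  }), path)
  invisible(path)
}

#' Read a dipolar trace file
#'
#' Two whitespace-separated columns: time and signal. Time units are
#' auto-detected by magnitude (values above 50 are taken as ns) unless
#' `unit` is given.
#'
#' @param path File path.
#' @param unit `"auto"`, `"us"` or `"ns"`.
#' @param normalize Rescale to 1 at the point nearest zero time.
#' @return A `deer_trace`.
#' @export
read_trace <- function(path, unit = c("auto", "us", "ns"),
                       normalize = TRUE) {
  unit <- match.arg(unit)
  m <- as.matrix(utils::read.table(path, comment.char = "%"))
  if (ncol(m) < 2) stop("expected 2 columns in ", path)
  t <- m[, 1]
  if (unit == "auto") unit <- if (max(abs(t)) > 50) "ns" else "us"
  if (unit == "ns") t <- t / 1000
  deer_trace(t, m[, 2], normalize = normalize)
}

#' Read a restraint definition file
#'
#' One restraint per line:
#' `site_i site_j mean_nm sigma_nm [distribution_file]`, comments with `%`
#' or `#`. Distribution paths are resolved relative to the restraint file.
#'
#' @param path File path.
#' @return List of `gaussian_restraint` objects.
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[%#]", lines) & nzchar(trimws(lines))
  out <- list()
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 4) {
      stop("malformed restraint at ", path, ":", ln,
           " (need: site_i site_j mean_nm sigma_nm [file])")
    }
    vals <- suppressWarnings(as.numeric(f[1:4]))
    if (any(is.na(vals))) {
      stop("non-numeric restraint field at ", path, ":", ln)
    }
    dist <- NULL
    if (length(f) >= 5) {
      dpath <- f[5]
      if (!file.exists(dpath)) dpath <- file.path(dirname(path), f[5])
      dist <- read_distribution(dpath)
    }
    out[[length(out) + 1L]] <- gaussian_restraint(
      vals[1], vals[2], mean = vals[3] * 10, sigma = vals[4] * 10,
      dist = dist)
  }
  if (length(out) == 0) stop("no restraints in ", path)
  out
}

#' Write a restraint definition file
#'
#' @param restraints List of `gaussian_restraint` objects.
#' @param path Output path.
#' @param dist_dir Optional directory into which full distributions are
#'   written (as `<site_i>_<site_j>.dat`), referenced from the restraint
#'   file.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path, dist_dir = NULL) {
  lines <- character(0)
  for (r in restraints) {
    base <- sprintf("%d %d %.6f %.6f", r$site_i, r$site_j,
                    r$mean / 10, r$sigma / 10)
    if (!is.null(r$dist) && !is.null(dist_dir)) {
      dir.create(dist_dir, showWarnings = FALSE, recursive = TRUE)
      fn <- sprintf("%d_%d.dat", r$site_i, r$site_j)
      write_distribution(r$dist, file.path(dist_dir, fn))
      base <- paste(base, file.path(dist_dir, fn))
    }
    lines <- c(lines, base)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sequence from a FASTA file
#'
#' @param path FASTA file.
#' @param which Record index (default 1).
#' @return Upper-case one-letter sequence string.
#' @export
read_sequence <- function(path, which = 1) {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  toupper(as.character(fa[[which]]))
}

#' Read anchor models from a PDB file
#'
#' Parses backbone atoms (N, CA, C, O) of all MODELs; multi-model files
#' yield one anchor per model. An optional residue-range truncation keeps
#' only the stated construct residues (e.g. `1:187` to drop a disordered
#' tail from a deposited structure).
#'
#' @param path PDB file.
#' @param residue_range Optional integer vector of residue numbers to keep.
#' @return List of anchor models (each with `xyz`, `atom`, `resno`,
#'   `resid`).
#' @export
read_anchor_models <- function(path, residue_range = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- pdb$atom$elety %in% c("N", "CA", "C", "O") &
    pdb$atom$type == "ATOM"
  if (!is.null(residue_range)) sel <- sel & pdb$atom$resno %in% residue_range
  if (!any(sel)) stop("no backbone atoms selected from ", path)
  idx <- which(sel)
  n_models <- nrow(pdb$xyz)
  lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
    list(xyz = xyz, atom = pdb$atom$elety[idx], resno = pdb$atom$resno[idx],
         resid = pdb$atom$resid[idx], chain = pdb$atom$chain[idx])
  })
}

#' Write an ensemble as multi-model PDB plus population table
#'
#' One MODEL per conformer with backbone ATOM records; the sidecar table
#' has `model_id population` lines.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param path_pdb,path_pop Output paths.
#' @return `path_pdb`, invisibly.
#' @export
write_ensemble <- function(ensemble, path_pdb, path_pop) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path_pdb, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    resid <- cf$resid %||% rep("ALA", nrow(cf$xyz))
    resid3 <- ifelse(nchar(resid) == 1, .aa1to3(resid), resid)
    # fixed PDB columns: name 13-16, altLoc 17, resName 18-20, chain 22,
    # resSeq 23-26, coordinates 31-54
    writeLines(sprintf(
      "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(cf$xyz)), sprintf(" %-3s", cf$atom), resid3,
      cf$resno, cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  writeLines(sprintf("%d %.8e", seq_along(ensemble$populations),
                     ensemble$populations), path_pop)
  invisible(path_pdb)
}

.aa1to3 <- function(aa) {
  tab <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- tab[aa]
  out[is.na(out)] <- "UNK"
  unname(out)
}

#' Read an ensemble from multi-model PDB plus population table
#'
#' @param path_pdb Multi-model PDB file.
#' @param path_pop Population table (`model_id population` lines); if
#'   missing, uniform populations are used with a warning.
#' @return A `conformer_ensemble`.
#' @export
read_ensemble <- function(path_pdb, path_pop = NULL) {
  models <- read_anchor_models(path_pdb)
  if (!is.null(path_pop) && file.exists(path_pop)) {
    tab <- utils::read.table(path_pop)
    if (nrow(tab) != length(models)) {
      stop("population table has ", nrow(tab), " rows for ",
           length(models), " models")
    }
    pops <- tab[[2]][order(tab[[1]])]
    if (abs(sum(pops) - 1) > 1e-6) {
      stop("populations sum to ", sum(pops), ", expected 1")
    }
  } else {
    if (!is.null(path_pop)) {
      warning("population file not found; assuming uniform populations")
    }
    pops <- NULL
  }
  conformer_ensemble(models, pops)
}

#' Write a machine-readable run report
#'
#' JSON object with seeds, inputs and the run's key scalars (geometric mean
#' overlap, conformer count, scaling parameters, ensemble width, radius of
#' gyration, ...).
#'
#' @param scalars Named list of scalar results.
#' @param path Output path.
#' @param seed Seed used for the run.
#' @param inputs Optional named list of input descriptors.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(scalars, path, seed = NA, inputs = list()) {
  report <- list(seed = seed, inputs = inputs, results = scalars)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
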