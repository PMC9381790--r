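# Structure and trajectory containers plus text-format I/O.
#
# Internal model: a `structure3d` is a particle table (name, residue number,
# residue name, chain) with an n x 3 coordinate matrix in Angstrom; a
# `trajectory3d` wraps one structure3d topology with an n x 3 x n_frames
# coordinate array and per-frame times in ns. Particle order in the topology
# is the canonical index order used by every frame.

#' Construct a structure of particles
#'
#' The basic container for atoms or coarse-grained beads. Coordinates are
#' always Angstrom. The (chain, residue number, particle name) triple must be
#' unique; particle order is canonical and shared with any trajectory built
#' on this topology.
#'
#' @param atoms data.frame with columns `name`, `resno`, `resname`, `chain`.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, Angstrom.
#' @param box optional numeric length-3 box edge lengths, Angstrom.
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, xyz, box = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "resno", "resname", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms lacks column(s): ", paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3L)
    stop("xyz must be ", nrow(atoms), " x 3")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, resno, name): ",
         paste(unique(key[duplicated(key)])[1:min(3, sum(duplicated(key)))],
               collapse = "; "))
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    stopifnot(length(box) == 3L, all(is.finite(box)), all(box > 0))
  }
  atoms$particle_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, xyz = xyz, box = box), class = "structure3d")
}

#' @export
print.structure3d <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat("structure3d:", nrow(x$atoms), "particles,", nres, "residues",
      if (!is.null(x$box)) sprintf("(box %.1f x %.1f x %.1f A)",
                                   x$box[1], x$box[2], x$box[3]) else "",
      "\n")
  invisible(x)
}

#' Number of particles in a structure or trajectory topology
#' @param x structure3d or trajectory3d.
#' @return integer count.
#' @export
n_particles <- function(x) {
  if (inherits(x, "trajectory3d")) x <- x$topology
  nrow(x$atoms)
}

#' Construct a trajectory
#'
#' @param topology structure3d giving particle identities and canonical order.
#' @param coords numeric array `n_particles x 3 x n_frames`, Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param box optional `n_frames x 3` matrix of per-frame box lengths.
#' @return object of class `trajectory3d`.
#' @export
trajectory3d <- function(topology, coords, times, box = NULL) {
  stopifnot(inherits(topology, "structure3d"))
  coords <- as.array(coords)
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  d <- dim(coords)
  if (d[1] != nrow(topology$atoms) || d[2] != 3L)
    stop("coords must be n_particles x 3 x n_frames")
  if (d[3] == 0L) stop("trajectory must contain at least one frame")
  times <- as.numeric(times)
  if (length(times) != d[3]) stop("times length must equal frame count")
  if (d[3] > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3L)
    if (nrow(box) == 1L) box <- box[rep(1L, d[3]), , drop = FALSE]
    stopifnot(nrow(box) == d[3])
  }
  structure(list(topology = topology, coords = coords, times = times,
                 box = box),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("trajectory3d:", n_frames(x), "frames x", n_particles(x), "particles;",
      sprintf("t = %g..%g ns\n", x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj trajectory3d.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one frame
#' @param traj trajectory3d.
#' @param i frame index (1-based).
#' @return n_particles x 3 matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

## ---- readers ---------------------------------------------------------------

#' Read a structure from PDB or GRO
#'
#' PDB files are parsed with \pkg{bio3d}; GRO files (GROMACS coordinate
#' format, nm) are parsed directly and converted to Angstrom on read.
#' Residue numbering is taken verbatim from the file.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return structure3d.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     gro = "gro", pdb = "pdb",
                     stop("cannot guess format from extension: ", path))
  }
  if (format == "pdb") read_structure_pdb(path) else read_structure_gro(path)
}

read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(name = trimws(at$elety),
                      resno = at$resno,
                      resname = trimws(at$resid),
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  if (anyNA(atoms$resno)) stop("malformed ATOM record (NA residue number) in ", path)
  structure3d(atoms, cbind(at$x, at$y, at$z))
}

read_structure_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file (too short): ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom count at line 2 of ", path)
  if (length(lines) < 2L + n + 1L)
    stop("GRO file truncated: expected ", n, " atom lines in ", path)
  rec <- lines[3:(2 + n)]
  resno <- suppressWarnings(as.integer(substr(rec, 1, 5)))
  resname <- trimws(substr(rec, 6, 10))
  name <- trimws(substr(rec, 11, 15))
  x <- suppressWarnings(as.numeric(substr(rec, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(rec, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(rec, 37, 44)))
  bad <- which(is.na(resno) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop("malformed GRO record at line ", 2L + bad[1], " of ", path)
  boxline <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L + n + 1L]),
                                                  "\\s+")[[1]]))
  box <- if (length(boxline) >= 3 && !anyNA(boxline[1:3])) boxline[1:3] * 10 else NULL
  atoms <- data.frame(name = name, resno = resno, resname = resname,
                      chain = "A", stringsAsFactors = FALSE)
  # GRO has no chain labels; residues sharing a number but not contiguous
  # stay distinguishable through resname in practice. nm -> Angstrom here.
  structure3d(atoms, cbind(x, y, z) * 10, box = box)
}

#' Read a trajectory from multi-model PDB or extended XYZ
#'
#' Two text formats are supported: multi-model PDB (`MODEL`/`ENDMDL` blocks)
#' and an extended-XYZ dialect whose comment line may carry
#' `Lattice="ax ay az bx by bz cx cy cz"` and `Time=<ns>` fields. When a
#' frame lacks time metadata, frames are timed `0, stride, 2*stride, ...` ns.
#'
#' @param path file path.
#' @param topology optional structure3d; required for `"xyz"`, checked
#'   against the file for `"pdb"`.
#' @param format `"auto"`, `"pdb"` or `"xyz"`.
#' @param stride_ns frame spacing used when the file carries no times
#'   (default 5 ns, a common coarse-grained save interval).
#' @return trajectory3d.
#' @export
read_trajectory <- function(path, topology = NULL,
                            format = c("auto", "pdb", "xyz"),
                            stride_ns = 5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", xyz = "xyz",
                     stop("cannot guess trajectory format: ", path))
  }
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    topo <- read_structure_pdb(path)
    nf <- nrow(pdb$xyz)
    coords <- array(NA_real_, c(nrow(topo$atoms), 3L, nf))
    for (i in seq_len(nf)) {
      coords[, , i] <- matrix(pdb$xyz[i, ], ncol = 3L, byrow = TRUE)
    }
    if (!is.null(topology)) {
      if (nrow(topology$atoms) != nrow(topo$atoms))
        stop("topology mismatch: file has ", nrow(topo$atoms),
             " particles, topology has ", nrow(topology$atoms))
      topo <- topology
    }
    trajectory3d(topo, coords, times = (seq_len(nf) - 1) * stride_ns)
  } else {
    read_trajectory_xyz(path, topology, stride_ns)
  }
}

read_trajectory_xyz <- function(path, topology, stride_ns) {
  if (is.null(topology))
    stop("extended-XYZ trajectories need an explicit topology")
  lines <- readLines(path)
  np <- nrow(topology$atoms)
  frames <- list(); times <- numeric(0); boxes <- list()
  i <- 1L; fidx <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed frame header at line ", i, " of ", path)
    fidx <- fidx + 1L
    if (n != np)
      stop("topology mismatch at frame ", fidx, ": file has ", n,
           " particles, topology has ", np)
    comment <- lines[i + 1L]
    if (i + 1L + n > length(lines))
      stop("trajectory truncated in frame ", fidx)
    rec <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rec), "\\s+")
    co <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(co)) stop("malformed coordinate record in frame ", fidx)
    frames[[fidx]] <- co
    tm <- regmatches(comment, regexec("Time=([-0-9.eE+]+)", comment))[[1]]
    times[fidx] <- if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_
    lt <- regmatches(comment, regexec("Lattice=\"([^\"]+)\"", comment))[[1]]
    boxes[[fidx]] <- if (length(lt) == 2L) {
      v <- as.numeric(strsplit(trimws(lt[2]), "\\s+")[[1]])
      if (length(v) == 9L) v[c(1, 5, 9)] else v[1:3]
    } else NULL
    i <- i + 2L + n
  }
  if (fidx == 0L) stop("no frames found in ", path)
  if (anyNA(times)) times <- (seq_len(fidx) - 1) * stride_ns
  coords <- array(unlist(frames), c(np, 3L, fidx))
  # frames were stored row-major per particle; rebuild properly
  for (k in seq_len(fidx)) coords[, , k] <- frames[[k]]
  box <- if (!is.null(boxes[[1]])) do.call(rbind, boxes) else NULL
  trajectory3d(topology, coords, times, box = box)
}

## ---- writers ---------------------------------------------------------------

format_pdb_atom <- function(serial, name, resname, chain, resno, xyz) {
  nm <- ifelse(nchar(name) <= 3L, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial %% 100000L, nm, substr(resname, 1, 4), substr(chain, 1, 1),
          resno %% 10000L, xyz[1], xyz[2], xyz[3])
}

#' Write a structure to PDB
#'
#' Writes ATOM records at standard 8.3f coordinate precision. Residue names
#' up to four characters are written in columns 18-21 (CHARMM-style), which
#' \pkg{bio3d} reads back unchanged.
#'
#' @param x structure3d.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  stopifnot(inherits(x, "structure3d"))
  at <- x$atoms
  lines <- vapply(seq_len(nrow(at)), function(i) {
    format_pdb_atom(i, at$name[i], at$resname[i], at$chain[i], at$resno[i],
                    x$xyz[i, ])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a trajectory to multi-model PDB or extended XYZ
#'
#' Round-trips through [read_trajectory()] reproduce coordinates to the
#' format precision (1e-3 Angstrom for PDB, full double precision controlled
#' by `digits` for XYZ).
#'
#' @param traj trajectory3d.
#' @param path output file path.
#' @param format `"pdb"` or `"xyz"`.
#' @param digits coordinate digits for the XYZ format.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "xyz"),
                             digits = 6) {
  stopifnot(inherits(traj, "trajectory3d"))
  format <- match.arg(format)
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  at <- traj$topology$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "pdb") {
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      co <- traj$coords[, , k]
      writeLines(vapply(seq_len(nrow(at)), function(i) {
        format_pdb_atom(i, at$name[i], at$resname[i], at$chain[i],
                        at$resno[i], co[i, ])
      }, character(1)), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    for (k in seq_len(nf)) {
      writeLines(as.character(nrow(at)), con)
      box <- if (!is.null(traj$box)) traj$box[k, ] else
        if (!is.null(traj$topology$box)) traj$topology$box else NULL
      lat <- if (!is.null(box))
        sprintf(' Lattice="%g 0 0 0 %g 0 0 0 %g"', box[1], box[2], box[3]) else ""
      writeLines(sprintf("Time=%g%s Properties=species:S:1:pos:R:3",
                         traj$times[k], lat), con)
      co <- traj$coords[, , k]
      writeLines(sprintf("%s %.*f %.*f %.*f", at$name, digits, co[, 1],
                         digits, co[, 2], digits, co[, 3]), con)
    }
  }
  invisible(path)
}
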