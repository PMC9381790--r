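# Per-frame membrane reference frame: leaflet assignment, the upper-leaflet
# phosphorus reference plane, and lipid heights above it.
#
# z is assumed to be the membrane normal; inputs must be pre-oriented.
# All heights ("lift", delta-z) are measured from the mean z of the
# upper-leaflet phosphate particles, recomputed every frame.

#' Index the lipids of a structure
#'
#' Identifies lipid residues by residue name and locates each lipid's
#' phosphate and choline particles. The result is the lipid handle consumed
#' by the leaflet, lift and salt-bridge analyses.
#'
#' @param structure structure3d (or trajectory3d, whose topology is used).
#' @param lipid_resnames residue names treated as lipids.
#' @param phosphate_name,choline_name particle names of the headgroup
#'   moieties (MARTINI-style defaults `"PO4"` and `"NC3"`; use `"P"`/`"N"`
#'   for all-atom structures).
#' @return object of class `lipid_index`: list with `ids` (chain:resno
#'   labels), `chain`, `resno`, `particles` (list of particle index
#'   vectors), `phosphate` and `choline` (particle index per lipid, NA when
#'   absent).
#' @export
lipid_index <- function(structure, lipid_resnames = c("POPC", "POP"),
                        phosphate_name = "PO4", choline_name = "NC3") {
  if (inherits(structure, "trajectory3d")) structure <- structure$topology
  stopifnot(inherits(structure, "structure3d"))
  at <- structure$atoms
  is_lip <- at$resname %in% lipid_resnames
  if (!any(is_lip)) stop("no lipid residues found (resnames: ",
                         paste(lipid_resnames, collapse = ", "), ")")
  key <- paste(at$chain, at$resno, sep = ":")
  lip_keys <- unique(key[is_lip])
  particles <- split(which(is_lip), factor(key[is_lip], levels = lip_keys))
  pick <- function(nm) {
    vapply(particles, function(idx) {
      hit <- idx[at$name[idx] == nm]
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  }
  phosphate <- pick(phosphate_name)
  choline <- pick(choline_name)
  parts <- strsplit(lip_keys, ":", fixed = TRUE)
  structure(list(ids = lip_keys,
                 chain = vapply(parts, `[`, "", 1L),
                 resno = as.integer(vapply(parts, `[`, "", 2L)),
                 particles = particles,
                 phosphate = phosphate,
                 choline = choline,
                 phosphate_name = phosphate_name,
                 choline_name = choline_name),
            class = "lipid_index")
}

#' @export
print.lipid_index <- function(x, ...) {
  cat("lipid_index:", length(x$ids), "lipids;",
      sum(!is.na(x$phosphate)), "with phosphate,",
      sum(!is.na(x$choline)), "with choline particles\n")
  invisible(x)
}

#' Assign lipids to leaflets
#'
#' A lipid belongs to the upper leaflet iff its phosphate z exceeds the
#' median phosphate z over all lipids in the frame. The per-frame median
#' split is robust to a lifted-lipid mound and is re-evaluated every frame.
#'
#' @param xyz n_particles x 3 coordinate matrix of one frame.
#' @param lipids lipid_index.
#' @return factor of `"upper"`/`"lower"` per lipid, named by lipid id.
#' @export
assign_leaflets <- function(xyz, lipids) {
  stopifnot(inherits(lipids, "lipid_index"))
  if (anyNA(lipids$phosphate)) {
    bad <- lipids$ids[is.na(lipids$phosphate)]
    stop("lipid(s) missing phosphate particle '", lipids$phosphate_name,
         "': ", paste(utils::head(bad, 3), collapse = ", "))
  }
  z <- xyz[lipids$phosphate, 3]
  lab <- ifelse(z > stats::median(z), "upper", "lower")
  factor(stats::setNames(lab, lipids$ids), levels = c("upper", "lower"))
}

#' Upper-leaflet phosphorus reference plane
#'
#' `z0` is the unweighted mean z of upper-leaflet phosphate particles. To
#' keep lipids that are currently lifted out of the leaflet from biasing the
#' plane, a one-pass trim drops lipids more than `exclusion_height_A` above
#' a provisional anchor before averaging. The anchor is the median upper
#' phosphate z: unlike a provisional mean it is not itself dragged upward
#' when several lifted lipids sit in a small leaflet, so the trim stays
#' effective. `exclusion_height_A = Inf` disables the trim (literal mean).
#'
#' @param xyz frame coordinates.
#' @param lipids lipid_index.
#' @param assignment leaflet factor from [assign_leaflets()]; computed here
#'   when omitted.
#' @param exclusion_height_A trim threshold, Angstrom (default 10).
#' @return list of class `membrane_plane`: `z0`, `n_used`, `n_excluded`.
#' @export
reference_plane <- function(xyz, lipids, assignment = NULL,
                            exclusion_height_A = 10) {
  if (is.null(assignment)) assignment <- assign_leaflets(xyz, lipids)
  up <- which(assignment == "upper")
  if (!length(up)) stop("no upper-leaflet lipids")
  z <- xyz[lipids$phosphate[up], 3]
  keep <- z <= stats::median(z) + exclusion_height_A
  if (!any(keep)) stop("all upper-leaflet lipids excluded from plane")
  z0 <- mean(z[keep])
  structure(list(z0 = z0, n_used = sum(keep), n_excluded = sum(!keep)),
            class = "membrane_plane")
}

#' @export
print.membrane_plane <- function(x, ...) {
  cat(sprintf("membrane_plane: z0 = %.3f A (%d phosphates, %d excluded)\n",
              x$z0, x$n_used, x$n_excluded))
  invisible(x)
}

#' Lipid height above the reference plane
#'
#' Delta-z of a lipid's phosphate particle above the upper-leaflet
#' phosphorus plane; negative values mean below the plane.
#'
#' @param xyz frame coordinates.
#' @param lipids lipid_index.
#' @param lipid_id lipid id (`"chain:resno"`) or integer position in
#'   `lipids$ids`.
#' @param plane membrane_plane for this frame.
#' @return numeric delta-z, Angstrom.
#' @export
lipid_height <- function(xyz, lipids, lipid_id, plane) {
  i <- if (is.character(lipid_id)) match(lipid_id, lipids$ids) else
    as.integer(lipid_id)
  if (is.na(i) || i < 1L || i > length(lipids$ids))
    stop("unknown lipid: ", lipid_id)
  p <- lipids$phosphate[i]
  if (is.na(p)) stop("lipid ", lipids$ids[i], " has no phosphate particle")
  xyz[p, 3] - plane$z0
}

# Vectorised per-frame heights for all lipids of a trajectory.
# Returns list(dz = n_lipids x n_frames matrix, z0 = numeric per frame,
# upper = logical n_lipids x n_frames).
height_matrix <- function(traj, lipids, exclusion_height_A = 10) {
  stopifnot(inherits(traj, "trajectory3d"))
  if (anyNA(lipids$phosphate))
    stop("lipid(s) missing phosphate particle")
  nf <- n_frames(traj)
  zP <- traj$coords[lipids$phosphate, 3, , drop = FALSE]
  zP <- matrix(zP, nrow = length(lipids$phosphate), ncol = nf)
  med <- apply(zP, 2L, stats::median)
  upper <- sweep(zP, 2L, med, ">")
  z0 <- vapply(seq_len(nf), function(k) {
    z <- zP[upper[, k], k]
    if (!length(z)) stop("no upper-leaflet lipids in frame ", k)
    keep <- z <= stats::median(z) + exclusion_height_A
    mean(z[keep])
  }, numeric(1))
  list(dz = sweep(zP, 2L, z0, "-"), z0 = z0, upper = upper)
}
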