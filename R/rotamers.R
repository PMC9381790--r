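# Backbone-independent rotamer library and side-chain geometry builder.
#
# Side-chain heavy atoms are placed by natural extension of reference
# frames (the NeRF construction) from an internal-coordinate table: each
# atom is defined by bond length, bond angle and a torsion that is either a
# chi dihedral (variable across rotamers) or fixed (ring closure, branch
# offsets, planar groups). Chi angles take the common staggered values
# (-60, 60, 180 degrees), giving at most 81 candidates per residue type.
# The placement contract is argmin-by-clash over the library, not fidelity
# to any particular published library.

# Place point D given A-B-C and internal coordinates (NeRF).
# torsion is the dihedral A-B-C-D in degrees.
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

# Internal-coordinate table: one row per heavy atom beyond CB.
# Torsion spec: chi index (1..4) with additive offset in degrees; chi = 0
# means fixed torsion equal to the offset.
sc_row <- function(atom, p, gp, ggp, bond, angle, chi, offset = 0) {
  data.frame(atom = atom, p = p, gp = gp, ggp = ggp, bond = bond,
             angle = angle, chi = chi, offset = offset,
             stringsAsFactors = FALSE)
}

sidechain_topology <- function() {
  rows <- function(...) do.call(rbind, list(...))
  list(
    ALA = NULL,
    GLY = NULL,
    SER = rows(sc_row("OG", "CB", "CA", "N", 1.41, 110.8, 1)),
    CYS = rows(sc_row("SG", "CB", "CA", "N", 1.81, 113.8, 1)),
    THR = rows(sc_row("OG1", "CB", "CA", "N", 1.43, 109.5, 1),
               sc_row("CG2", "CB", "CA", "N", 1.52, 110.5, 1, -120)),
    VAL = rows(sc_row("CG1", "CB", "CA", "N", 1.53, 110.5, 1),
               sc_row("CG2", "CB", "CA", "N", 1.53, 110.5, 1, 122)),
    LEU = rows(sc_row("CG", "CB", "CA", "N", 1.53, 115.6, 1),
               sc_row("CD1", "CG", "CB", "CA", 1.53, 110.7, 2),
               sc_row("CD2", "CG", "CB", "CA", 1.53, 110.7, 2, 122)),
    ILE = rows(sc_row("CG1", "CB", "CA", "N", 1.53, 110.4, 1),
               sc_row("CG2", "CB", "CA", "N", 1.53, 110.5, 1, -122),
               sc_row("CD1", "CG1", "CB", "CA", 1.53, 113.8, 2)),
    PRO = rows(sc_row("CG", "CB", "CA", "N", 1.50, 104.5, 1),
               sc_row("CD", "CG", "CB", "CA", 1.51, 105.5, 2)),
    MET = rows(sc_row("CG", "CB", "CA", "N", 1.53, 114.1, 1),
               sc_row("SD", "CG", "CB", "CA", 1.80, 112.7, 2),
               sc_row("CE", "SD", "CG", "CB", 1.79, 100.8, 3)),
    ASP = rows(sc_row("CG", "CB", "CA", "N", 1.52, 112.6, 1),
               sc_row("OD1", "CG", "CB", "CA", 1.25, 118.5, 2),
               sc_row("OD2", "CG", "CB", "CA", 1.25, 118.5, 2, 180)),
    ASN = rows(sc_row("CG", "CB", "CA", "N", 1.52, 112.6, 1),
               sc_row("OD1", "CG", "CB", "CA", 1.23, 120.8, 2),
               sc_row("ND2", "CG", "CB", "CA", 1.33, 116.4, 2, 180)),
    GLU = rows(sc_row("CG", "CB", "CA", "N", 1.53, 114.1, 1),
               sc_row("CD", "CG", "CB", "CA", 1.52, 112.6, 2),
               sc_row("OE1", "CD", "CG", "CB", 1.25, 118.5, 3),
               sc_row("OE2", "CD", "CG", "CB", 1.25, 118.5, 3, 180)),
    GLN = rows(sc_row("CG", "CB", "CA", "N", 1.53, 114.1, 1),
               sc_row("CD", "CG", "CB", "CA", 1.52, 112.6, 2),
               sc_row("OE1", "CD", "CG", "CB", 1.23, 120.8, 3),
               sc_row("NE2", "CD", "CG", "CB", 1.33, 116.4, 3, 180)),
    LYS = rows(sc_row("CG", "CB", "CA", "N", 1.53, 114.1, 1),
               sc_row("CD", "CG", "CB", "CA", 1.53, 111.3, 2),
               sc_row("CE", "CD", "CG", "CB", 1.53, 111.3, 3),
               sc_row("NZ", "CE", "CD", "CG", 1.49, 111.9, 4)),
    ARG = rows(sc_row("CG", "CB", "CA", "N", 1.53, 114.1, 1),
               sc_row("CD", "CG", "CB", "CA", 1.53, 111.3, 2),
               sc_row("NE", "CD", "CG", "CB", 1.46, 112.0, 3),
               sc_row("CZ", "NE", "CD", "CG", 1.33, 124.2, 4),
               sc_row("NH1", "CZ", "NE", "CD", 1.33, 120.0, 0, 0),
               sc_row("NH2", "CZ", "NE", "CD", 1.33, 120.0, 0, 180)),
    PHE = rows(sc_row("CG", "CB", "CA", "N", 1.51, 113.8, 1),
               sc_row("CD1", "CG", "CB", "CA", 1.39, 120.8, 2),
               sc_row("CD2", "CG", "CB", "CA", 1.39, 120.8, 2, 180),
               sc_row("CE1", "CD1", "CG", "CB", 1.39, 120.8, 0, 180),
               sc_row("CE2", "CD2", "CG", "CB", 1.39, 120.8, 0, 180),
               sc_row("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0, 0)),
    TYR = rows(sc_row("CG", "CB", "CA", "N", 1.51, 113.8, 1),
               sc_row("CD1", "CG", "CB", "CA", 1.39, 120.8, 2),
               sc_row("CD2", "CG", "CB", "CA", 1.39, 120.8, 2, 180),
               sc_row("CE1", "CD1", "CG", "CB", 1.39, 120.8, 0, 180),
               sc_row("CE2", "CD2", "CG", "CB", 1.39, 120.8, 0, 180),
               sc_row("CZ", "CE1", "CD1", "CG", 1.39, 120.0, 0, 0),
               sc_row("OH", "CZ", "CE1", "CD1", 1.38, 119.9, 0, 180)),
    HIS = rows(sc_row("CG", "CB", "CA", "N", 1.49, 113.8, 1),
               sc_row("ND1", "CG", "CB", "CA", 1.38, 122.7, 2),
               sc_row("CD2", "CG", "CB", "CA", 1.36, 131.0, 2, 180),
               sc_row("CE1", "ND1", "CG", "CB", 1.32, 109.0, 0, 180),
               sc_row("NE2", "CD2", "CG", "CB", 1.37, 107.0, 0, 180)),
    TRP = rows(sc_row("CG", "CB", "CA", "N", 1.50, 113.6, 1),
               sc_row("CD1", "CG", "CB", "CA", 1.37, 127.0, 2),
               sc_row("CD2", "CG", "CB", "CA", 1.43, 126.6, 2, 180),
               sc_row("NE1", "CD1", "CG", "CB", 1.38, 110.0, 0, 180),
               sc_row("CE2", "CD2", "CG", "CB", 1.41, 107.0, 0, 180),
               sc_row("CE3", "CD2", "CG", "CB", 1.40, 133.9, 0, 0),
               sc_row("CZ2", "CE2", "CD2", "CG", 1.40, 122.4, 0, 180),
               sc_row("CZ3", "CE3", "CD2", "CG", 1.39, 118.7, 0, 180),
               sc_row("CH2", "CZ2", "CE2", "CD2", 1.37, 117.5, 0, 0)))
}

n_chi <- function(resname) {
  topo <- sidechain_topology()[[resname]]
  if (is.null(topo)) 0L else max(0L, topo$chi)
}

#' Default backbone-independent rotamer library
#'
#' For each residue type, candidate chi-angle vectors built from the
#' staggered values -60, 60 and 180 degrees (proline uses its two ring
#' puckers). Alanine and glycine each have one trivial candidate. At most
#' 81 candidates per type (lysine, arginine).
#'
#' @return named list; each element a list of numeric chi vectors in
#'   library order (the tie-break order for clash-score ties).
#' @export
default_rotamer_library <- function() {
  types <- names(sidechain_topology())
  lib <- lapply(types, function(rn) {
    if (rn == "PRO") return(list(c(25, -35), c(-25, 35)))
    k <- n_chi(rn)
    if (k == 0L) return(list(numeric(0)))
    grid <- do.call(expand.grid, rep(list(c(-60, 60, 180)), k))
    lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  })
  stats::setNames(lib, types)
}

# Build side-chain heavy atoms (including CB) for a residue type at given
# chi angles, on a backbone defined by N, CA, C positions.
# Returns a matrix with rownames = atom names, or NULL for glycine.
build_side_chain <- function(resname, chi, N, CA, C) {
  resname <- toupper(resname)
  topo_all <- sidechain_topology()
  if (!resname %in% names(topo_all)) stop("unknown residue type: ", resname)
  if (resname == "GLY") return(NULL)
  # CB off the backbone: dihedral C-N-CA-CB ~ -122.6 deg (L-amino acid)
  pos <- list(N = N, CA = CA, C = C)
  pos$CB <- nerf_place(C, N, CA, 1.53, 110.5, -122.6)
  topo <- topo_all[[resname]]
  if (!is.null(topo)) {
    need <- max(0L, topo$chi)
    if (length(chi) < need)
      stop(resname, " needs ", need, " chi angle(s), got ", length(chi))
    for (i in seq_len(nrow(topo))) {
      tors <- if (topo$chi[i] > 0) chi[topo$chi[i]] + topo$offset[i] else
        topo$offset[i]
      pos[[topo$atom[i]]] <- nerf_place(pos[[topo$ggp[i]]],
                                        pos[[topo$gp[i]]],
                                        pos[[topo$p[i]]],
                                        topo$bond[i], topo$angle[i], tors)
    }
  }
  nm <- setdiff(names(pos), c("N", "CA", "C"))
  out <- do.call(rbind, pos[nm])
  rownames(out) <- nm
  out
}
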