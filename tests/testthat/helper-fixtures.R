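# In-code fixtures shared across tests. Everything is built
# programmatically; no binary files.

# Minimal lipid-only structure: each lipid has a PO4 bead at the given
# position and an NC3 bead 3.5 A above it (chain L, resno 1..n).
make_lipid_struct <- function(po4_xyz, box = NULL) {
  po4_xyz <- matrix(po4_xyz, ncol = 3)
  n <- nrow(po4_xyz)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(name = c("PO4", "NC3"), resno = i, resname = "POPC",
               chain = "L", stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(po4_xyz[i, ], po4_xyz[i, ] + c(0, 0, 3.5))))
  structure3d(atoms, xyz, box = box)
}

# Wrap a structure and a list of per-frame coordinate matrices into a
# trajectory (times 0, 5, 10, ... ns).
make_traj <- function(struct, frames) {
  coords <- array(unlist(frames), c(nrow(struct$atoms), 3, length(frames)))
  for (k in seq_along(frames)) coords[, , k] <- frames[[k]]
  trajectory3d(struct, coords, times = (seq_along(frames) - 1) * 5)
}

# Straight poly-peptide backbone (N, CA, C, O per residue) along z, for
# homology tests. `codes` are one-letter amino acids.
make_backbone_template <- function(codes, chain = "A", rise = 3.4) {
  n <- length(codes)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(name = c("N", "CA", "C", "O"), resno = i,
               resname = bio3d::aa123(codes[i]), chain = chain,
               stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, lapply(seq_len(n), function(i) {
    z <- i * rise
    rbind(c(0.0, 1.2, z), c(0.0, 0.0, z + 1.0), c(1.3, 0.0, z + 1.9),
          c(2.3, 0.7, z + 1.9))
  }))
  structure3d(atoms, xyz)
}

# Forge a threaded model holding one flagged substitution at `resno` of a
# backbone template, plus optional extra environment atoms.
make_toy_model <- function(template, resno, to_code, env_xyz = NULL) {
  st <- template
  if (!is.null(env_xyz)) {
    env_xyz <- matrix(env_xyz, ncol = 3)
    extra <- data.frame(name = paste0("X", seq_len(nrow(env_xyz))),
                        resno = 9000L + seq_len(nrow(env_xyz)),
                        resname = "ENV", chain = "Z",
                        stringsAsFactors = FALSE)
    st <- structure3d(rbind(st$atoms[, c("name", "resno", "resname", "chain")],
                            extra),
                      rbind(st$xyz, env_xyz))
  }
  from <- bio3d::aa321(st$atoms$resname[st$atoms$resno == resno][1])
  structure(list(structure = st,
                 substitutions = data.frame(resno = resno, from = from,
                                            to = to_code,
                                            stringsAsFactors = FALSE),
                 dropped_target_insertions = integer(0),
                 clash_report = NULL),
            class = "threaded_model")
}

# Independent brute-force contact scan: minimum pairwise distance between
# every moiety bead of the selected lipids and every side-chain particle
# of every residue, via a plain double loop. The O(N^2) oracle.
brute_force_contacts <- function(traj, frame, residues, lipids,
                                 cutoff_A = 6) {
  at <- traj$topology$atoms
  co <- traj$coords[, , frame]
  res <- as.data.frame(residues)
  bb <- c("BB", "N", "CA", "C", "O", "OXT", "H", "HA", "HN")
  out <- list()
  for (r in seq_len(nrow(res))) {
    sc <- which(at$chain == res$chain[r] & at$resno == res$resno[r] &
                  !(at$name %in% bb))
    for (m in c("choline", "phosphate")) {
      bead <- if (m == "choline") lipids$choline else lipids$phosphate
      for (li in seq_along(lipids$ids)) {
        dmin <- Inf
        for (s in sc) {
          d <- sqrt(sum((co[bead[li], ] - co[s, ])^2))
          if (d < dmin) dmin <- d
        }
        out[[length(out) + 1L]] <- data.frame(
          chain = res$chain[r], resno = res$resno[r], moiety = m,
          lipid = lipids$ids[li], min_distance = dmin,
          contact = dmin <= cutoff_A, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
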