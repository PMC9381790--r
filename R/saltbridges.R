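# Salt-bridge contacts between lipid headgroup moieties (choline, phosphate)
# and charged residue side chains: per-frame contacts, occupancy tables with
# replica pooling, and the sequential gateway ladder followed by an
# extracted lipid.
#
# A contact exists when the minimum particle-pair distance between the
# moiety bead(s) and the residue's side-chain particles is <= the cutoff
# (default 6 A). Minimum-pair distance (not centre of mass) is the only
# convention under which one cutoff is meaningful for both coarse-grained
# and all-atom inputs.

backbone_names <- c("BB", "N", "CA", "C", "O", "OXT", "H", "HA", "HN")

# Particle indices of a residue's side chain (all non-backbone particles).
sidechain_indices <- function(structure, chain, resno) {
  at <- structure$atoms
  idx <- which(at$chain == chain & at$resno == resno)
  if (!length(idx)) stop("residue ", chain, ":", resno, " not in structure")
  sc <- idx[!(at$name[idx] %in% backbone_names)]
  if (!length(sc))
    stop("residue ", chain, ":", resno,
         " has no side-chain particles (glycine cannot form a salt bridge)")
  sc
}

moiety_particle <- function(lipids, i, moiety) {
  p <- switch(moiety, choline = lipids$choline[i],
              phosphate = lipids$phosphate[i],
              stop("unknown moiety: ", moiety))
  if (is.na(p)) stop("lipid ", lipids$ids[i], " has no ", moiety, " particle")
  p
}

#' Salt-bridge contacts in one frame
#'
#' For every (residue, moiety, lipid) combination, computes the minimum
#' distance between the lipid's moiety particle and the residue's
#' side-chain particles and flags contacts at the cutoff.
#'
#' @param traj trajectory3d.
#' @param frame frame index.
#' @param residues residue_set of charged residues (side chains must exist;
#'   a glycine in the set is an error).
#' @param lipids lipid_index.
#' @param lipid_ids lipid ids or positions to test (default: all lipids).
#' @param cutoff_A contact cutoff, Angstrom (default 6).
#' @param all_distances when `TRUE`, rows for non-contacts are kept.
#' @return data.frame with columns `frame`, `chain`, `resno`, `moiety`,
#'   `lipid`, `min_distance`, `contact`.
#' @export
contacts_in_frame <- function(traj, frame, residues, lipids = NULL,
                              lipid_ids = NULL, cutoff_A = 6,
                              all_distances = FALSE) {
  if (is.null(lipids)) lipids <- lipid_index(traj)
  res <- as.data.frame(residues)
  li <- if (is.null(lipid_ids)) seq_along(lipids$ids)
  else if (is.character(lipid_ids)) match(lipid_ids, lipids$ids)
  else as.integer(lipid_ids)
  if (anyNA(li)) stop("unknown lipid id(s)")
  co <- traj$coords[, , frame]
  out <- list()
  for (r in seq_len(nrow(res))) {
    sc <- sidechain_indices(traj$topology, res$chain[r], res$resno[r])
    sc_xyz <- co[sc, , drop = FALSE]
    for (moiety in c("choline", "phosphate")) {
      mp <- vapply(li, function(i) moiety_particle(lipids, i, moiety),
                   integer(1))
      d2 <- pairwise_dist2(co[mp, , drop = FALSE], sc_xyz)
      dmin <- sqrt(apply(d2, 1L, min))
      out[[length(out) + 1L]] <- data.frame(
        frame = frame, chain = res$chain[r], resno = res$resno[r],
        moiety = moiety, lipid = lipids$ids[li], min_distance = dmin,
        contact = dmin <= cutoff_A, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (!all_distances) out <- out[out$contact, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-frame contact indicator for one (residue, moiety) against a fixed
# lipid selection, vectorised over frames. Returns logical n_frames vector
# (and min distances when wanted).
contact_series <- function(traj, sc_idx, moiety_idx, cutoff_A,
                           frames = NULL, distances = FALSE) {
  nf <- n_frames(traj)
  if (is.null(frames)) frames <- seq_len(nf)
  L <- length(moiety_idx)
  A <- traj$coords[moiety_idx, , frames, drop = FALSE]  # L x 3 x F
  dmin2 <- NULL
  for (b in sc_idx) {
    B <- traj$coords[b, , frames, drop = FALSE]         # 1 x 3 x F
    d2 <- matrix(0, L, length(frames))
    for (d in 1:3) {
      Ad <- matrix(A[, d, ], nrow = L)
      d2 <- d2 + sweep(Ad, 2L, B[1, d, ], "-")^2
    }
    dmin2 <- if (is.null(dmin2)) d2 else pmin(dmin2, d2)
  }
  m2 <- apply(dmin2, 2L, min)                           # over lipids
  res <- m2 <= cutoff_A^2
  if (distances) attr(res, "min_distance") <- sqrt(m2)
  res
}

#' Frame window covering the last fraction of a trajectory
#'
#' Convenience for windows such as "the last half of the run" (the common
#' equilibrated-tail convention, e.g. the last 5 us of a 10 us simulation).
#'
#' @param traj trajectory3d.
#' @param fraction fraction of frames, from the end, in (0, 1].
#' @return integer frame indices.
#' @export
last_fraction_frames <- function(traj, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  nf <- n_frames(traj)
  n <- max(1L, round(nf * fraction))
  seq.int(nf - n + 1L, nf)
}

#' Salt-bridge occupancy table
#'
#' For each (residue, moiety), the occupancy is the fraction of window
#' frames in which at least one selected lipid's moiety particle lies
#' within the cutoff of the residue's side chain. With several replicas,
#' per-replica rows are emitted together with pooled rows whose occupancy
#' is the frame-weighted mean of the replica occupancies.
#'
#' @param trajs a trajectory3d or a list of them (replicas).
#' @param residues residue_set of charged residues.
#' @param lipids lipid_index, or a list (one per replica); computed from
#'   each topology when omitted.
#' @param selection lipid selection per replica: `"all"` (default), lipid
#'   ids, positions, or an [track_extracted()] trace (its lipid only).
#' @param cutoff_A contact cutoff (default 6 A).
#' @param frames frame window: `NULL` (all), integer indices, or a fraction
#'   in (0,1) meaning the last fraction of each replica.
#' @return data.frame of class `occupancy_table`: `replica`, `chain`,
#'   `resno`, `moiety`, `n_contact`, `n_frames`, `occupancy`.
#' @export
sb_occupancy <- function(trajs, residues, lipids = NULL, selection = "all",
                         cutoff_A = 6, frames = NULL) {
  if (inherits(trajs, "trajectory3d")) trajs <- list(trajs)
  nrep <- length(trajs)
  if (!nrep) stop("empty frame window: no replicas")
  if (!is.null(lipids) && inherits(lipids, "lipid_index"))
    lipids <- rep(list(lipids), nrep)
  res <- as.data.frame(residues)
  rows <- list()
  for (rep_i in seq_len(nrep)) {
    traj <- trajs[[rep_i]]
    lip <- if (is.null(lipids)) lipid_index(traj) else lipids[[rep_i]]
    fr <- if (is.null(frames)) seq_len(n_frames(traj))
    else if (length(frames) == 1L && frames > 0 && frames < 1)
      last_fraction_frames(traj, frames)
    else as.integer(frames)
    if (!length(fr)) stop("empty frame window")
    sel_idx <- if (inherits(selection, "extraction_trace"))
      match(selection$lipid_id, lip$ids)
    else if (identical(selection, "all")) seq_along(lip$ids)
    else if (is.character(selection)) match(selection, lip$ids)
    else as.integer(selection)
    if (anyNA(sel_idx)) stop("unknown lipid in selection")
    for (r in seq_len(nrow(res))) {
      sc <- sidechain_indices(traj$topology, res$chain[r], res$resno[r])
      for (moiety in c("choline", "phosphate")) {
        mp <- vapply(sel_idx, function(i) moiety_particle(lip, i, moiety),
                     integer(1))
        hit <- contact_series(traj, sc, mp, cutoff_A, fr)
        rows[[length(rows) + 1L]] <- data.frame(
          replica = rep_i, chain = res$chain[r], resno = res$resno[r],
          moiety = moiety, n_contact = sum(hit), n_frames = length(fr),
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$occupancy <- tab$n_contact / tab$n_frames
  pooled <- stats::aggregate(cbind(n_contact, n_frames) ~ chain + resno +
                               moiety, data = tab, FUN = sum)
  pooled$replica <- "pooled"
  pooled$occupancy <- pooled$n_contact / pooled$n_frames
  tab$replica <- as.character(tab$replica)
  out <- rbind(tab[, c("replica", "chain", "resno", "moiety", "n_contact",
                       "n_frames", "occupancy")],
               pooled[, c("replica", "chain", "resno", "moiety", "n_contact",
                          "n_frames", "occupancy")])
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Sequential salt-bridge ladder of an extracted lipid
#'
#' Detects, for each ladder residue, the first frame at which the traced
#' lipid maintains a contact for at least `sustain_frames` consecutive
#' frames, and reports the lipid's height above the membrane plane at that
#' onset. Residues are reported in onset order; residues that never form a
#' sustained contact are flagged absent. The classic wild-type ladder has
#' the extracted lipid engaging D571, D575, E584 and D585 at roughly 10,
#' 12, 15 and 17 A of lift.
#'
#' @param trace extraction_trace from [track_extracted()].
#' @param traj trajectory3d the trace was computed on.
#' @param residues residue_set of ladder residues (default: D571, D575,
#'   E584, D585 on the chain of the trace's nearest-residue table, else
#'   chain `"A"`).
#' @param lipids lipid_index.
#' @param cutoff_A contact cutoff (default 6 A).
#' @param sustain_frames consecutive frames required (default 2; use 1 for
#'   a literal single-frame reading).
#' @return data.frame of class `ladder_report`, ordered by onset frame:
#'   `chain`, `resno`, `onset_frame`, `dz_at_onset`, `present`; attribute
#'   `"in_expected_order"` compares present residues against the order of
#'   `residues`.
#' @export
sb_ladder <- function(trace, traj, residues = NULL, lipids = NULL,
                      cutoff_A = 6, sustain_frames = 2) {
  if (is.null(trace) || !inherits(trace, "extraction_trace"))
    stop("trace must be an extraction_trace")
  if (is.null(lipids)) lipids <- lipid_index(traj)
  if (is.null(residues)) {
    ch <- if (!is.null(trace$nearest_residue)) {
      trace$nearest_residue$chain[1]
    } else {
      # default ladder residues: find the chain that carries residue 571
      at <- traj$topology$atoms
      cand <- unique(at$chain[at$resno == 571L & !(at$resname %in%
                                                    c("POPC", "POP"))])
      if (!length(cand)) stop("cannot locate ladder residues; pass `residues`")
      cand[1]
    }
    residues <- residue_set(c(571, 575, 584, 585), ch, name = "ladder")
  }
  res <- as.data.frame(residues)
  lip_i <- match(trace$lipid_id, lipids$ids)
  rows <- lapply(seq_len(nrow(res)), function(r) {
    sc <- sidechain_indices(traj$topology, res$chain[r], res$resno[r])
    hit <- logical(length(trace$frames))
    for (moiety in c("choline", "phosphate")) {
      mp <- moiety_particle(lipids, lip_i, moiety)
      hit <- hit | contact_series(traj, sc, mp, cutoff_A, trace$frames)
    }
    onset <- NA_integer_
    run <- rle(hit)
    ends <- cumsum(run$lengths)
    ok <- which(run$values & run$lengths >= sustain_frames)
    if (length(ok)) onset <- ends[ok[1]] - run$lengths[ok[1]] + 1L
    data.frame(chain = res$chain[r], resno = res$resno[r],
               onset_frame = if (is.na(onset)) NA_integer_ else
                 trace$frames[onset],
               dz_at_onset = if (is.na(onset)) NA_real_ else trace$dz[onset],
               present = !is.na(onset), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$onset_frame, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  expected <- res$resno
  observed <- out$resno[out$present]
  attr(out, "in_expected_order") <-
    identical(observed, expected[expected %in% observed])
  class(out) <- c("ladder_report", "data.frame")
  out
}
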