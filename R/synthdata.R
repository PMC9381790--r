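# Seeded synthetic bilayer + protein trajectories with planted ground
# truth.
#
# The generator emulates the statistical structure the analyses assume —
# two flat leaflets of 12-bead pseudo-POPC, a charged gateway loop with
# author numbering hovering above the upper leaflet, Bernoulli salt-bridge
# contact schedules, a deterministic lift schedule for one extracted lipid,
# and an optional lifted-lipid mound — not membrane physics. There are no
# forces or thermostats; every planted event is realised geometrically with
# an exact guard band (contact distance 5.0 A <= the 6 A cutoff,
# counter-moiety at 8.5 A > 8 A), so analysis outcomes are decidable
# despite positional noise.

#' Synthetic 29-residue gateway sequence
#'
#' A synthetic stand-in for the gateway loop sequence (residues 564-592):
#' the 11 charged residues sit at their published positions (E564, R565,
#' K568, K570, D571, D575, R579, D581, E584, D585, R587) and the remaining
#' positions are filled so the class census matches the published
#' composition (5 basic, 6 acidic, 5 aromatic, 7 hydrophobic, 29 total).
#' It is not the real ABCA1 sequence, which the analyses never require.
#'
#' @return named character vector, names `"564"`..`"592"`.
#' @export
synthetic_gateway_sequence <- function() {
  codes <- c("E", "R", "F", "L", "K", "W", "K", "D", "A", "S", "Y", "D",
             "V", "G", "N", "R", "I", "D", "F", "L", "E", "D", "P", "R",
             "S", "L", "W", "M", "Q")
  stats::setNames(codes, as.character(564:592))
}

#' Specification of a synthetic trajectory
#'
#' Bundles and validates all generator settings. The defaults are the
#' desk-scale study conditions: 128 lipids, 1000 frames saved every 5 ns,
#' 0.5 A positional noise, and the two headline planted occupancies
#' (phosphate contact with K568 at p = 0.77, choline contact with D571 at
#' p = 0.39). A full-scale run uses `n_lipids = 792` and 2000 frames.
#'
#' @param n_lipids even lipid count, split equally between leaflets.
#' @param box_xy lateral box edge, Angstrom (default: grid-determined).
#' @param leaflet_gap distance between the two phosphate planes, Angstrom.
#' @param noise_sigma per-coordinate Gaussian jitter, Angstrom.
#' @param n_frames frames to emit.
#' @param frame_stride_ns saved-frame spacing, ns.
#' @param seed RNG seed; same seed, same trajectory and truth.
#' @param planted_occupancies data.frame `resno`, `moiety`, `p`, or `NULL`
#'   for none. Defaults to the two headline schedules above.
#' @param lift_schedule data.frame `from`, `to`, `dz` (frame ranges,
#'   target heights >= 0) for one extracted lipid, or `NULL`.
#' @param contact_schedule data.frame `resno`, `moiety`, `from`, `to`:
#'   deterministic contacts between those residues and the extracted lipid
#'   (the ladder), or `NULL`.
#' @param mound_size number of lipids planted as a lifted mound (0 = none).
#' @param mound_heights heights of the mound lipids, recycled to
#'   `mound_size`.
#' @param gateway_sequence named code vector for residues 564-592.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lipids = 128, box_xy = NULL, leaflet_gap = 38,
                           noise_sigma = 0.5, n_frames = 1000,
                           frame_stride_ns = 5, seed = 1,
                           planted_occupancies = default_planted_occupancies(),
                           lift_schedule = NULL, contact_schedule = NULL,
                           mound_size = 0,
                           mound_heights = seq(10.5, 11.9, length.out = 5),
                           gateway_sequence = synthetic_gateway_sequence()) {
  if (n_lipids < 2 || n_lipids %% 2 != 0) stop("n_lipids must be even, >= 2")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (leaflet_gap <= 0 || frame_stride_ns <= 0)
    stop("leaflet_gap and frame_stride_ns must be positive")
  spacing <- 8.2
  side <- ceiling(sqrt(n_lipids / 2))
  min_box <- side * spacing
  box_xy <- box_xy %||% min_box
  if (box_xy < min_box - 1e-9)
    stop("box too small: ", n_lipids / 2, " lipids per leaflet need >= ",
         round(min_box, 1), " A at ", spacing, " A spacing")
  if (!is.null(planted_occupancies)) {
    po <- planted_occupancies
    stopifnot(is.data.frame(po), all(c("resno", "moiety", "p") %in% names(po)))
    if (any(po$p < 0 | po$p > 1)) stop("planted probabilities must lie in [0, 1]")
    if (!all(po$moiety %in% c("choline", "phosphate")))
      stop("moiety must be 'choline' or 'phosphate'")
    if (!all(as.character(po$resno) %in% names(gateway_sequence)))
      stop("planted residue outside the gateway range")
  }
  if (!is.null(lift_schedule)) {
    ls <- lift_schedule
    stopifnot(is.data.frame(ls), all(c("from", "to", "dz") %in% names(ls)))
    if (any(ls$dz < 0)) stop("lift schedule heights must be >= 0")
    if (any(ls$from > ls$to) || any(ls$from < 1) || any(ls$to > n_frames))
      stop("lift schedule frame ranges out of bounds")
  }
  if (!is.null(contact_schedule)) {
    cs <- contact_schedule
    stopifnot(is.data.frame(cs),
              all(c("resno", "moiety", "from", "to") %in% names(cs)))
    if (is.null(lift_schedule))
      stop("contact_schedule needs a lift_schedule (an extracted lipid)")
    if (!is.null(planted_occupancies) &&
        any(cs$resno %in% planted_occupancies$resno))
      stop("a residue cannot carry both a Bernoulli occupancy and a ",
           "deterministic contact schedule (its side-chain bead cannot ",
           "satisfy two lipids)")
  }
  structure(list(n_lipids = n_lipids, box_xy = box_xy,
                 leaflet_gap = leaflet_gap, noise_sigma = noise_sigma,
                 n_frames = n_frames, frame_stride_ns = frame_stride_ns,
                 seed = seed, planted_occupancies = planted_occupancies,
                 lift_schedule = lift_schedule,
                 contact_schedule = contact_schedule,
                 mound_size = mound_size,
                 mound_heights = rep_len(mound_heights, max(1, mound_size)),
                 gateway_sequence = gateway_sequence, spacing = spacing),
            class = "synthetic_spec")
}

#' Default planted contact schedules
#'
#' The two headline salt-bridge occupancies: phosphate with K568 at
#' p = 0.77 and choline with D571 at p = 0.39.
#'
#' @return data.frame `resno`, `moiety`, `p`.
#' @export
default_planted_occupancies <- function() {
  data.frame(resno = c(568L, 571L), moiety = c("phosphate", "choline"),
             p = c(0.77, 0.39), stringsAsFactors = FALSE)
}

#' Ladder plan: lift schedule plus contact schedule
#'
#' Partitions the frame range into a baseline block followed by four
#' plateau blocks at 10, 12, 15 and 17 A, with deterministic choline
#' contacts to D571, D575, E584 and D585 switched on during the respective
#' blocks — the wild-type extraction ladder.
#'
#' @param n_frames total frames.
#' @param dz plateau heights (default `c(10, 12, 15, 17)`).
#' @param resno ladder residues in plateau order.
#' @return list with `lift_schedule` and `contact_schedule` data.frames,
#'   ready for [synthetic_spec()].
#' @export
ladder_plan <- function(n_frames, dz = c(10, 12, 15, 17),
                        resno = c(571L, 575L, 584L, 585L)) {
  stopifnot(length(dz) == length(resno), n_frames >= 5 * length(dz) + 5)
  nb <- length(dz) + 1L
  edges <- round(seq(0, n_frames, length.out = nb + 1L))
  from <- edges[-(nb + 1L)] + 1L
  to <- edges[-1]
  list(lift_schedule = data.frame(from = from[-1], to = to[-1], dz = dz),
       contact_schedule = data.frame(resno = resno, moiety = "choline",
                                     from = from[-1], to = to[-1],
                                     stringsAsFactors = FALSE))
}

# Bead template of one pseudo-POPC: names and offsets (x, y, z) relative to
# the phosphate, for the upper leaflet (z flipped for the lower).
lipid_template <- function() {
  cbind(x = c(0, 0, 0.4, -0.4, 0.8, 0.8, 0.8, 0.8, -0.8, -0.8, -0.8, -0.8),
        y = c(0, 0, 0.4, -0.4, 0, 0, 0, 0, 0, 0, 0, 0),
        z = c(3.5, 0, -3, -4.5, -7.5, -10.5, -13.5, -16.5,
              -7.5, -10.5, -13.5, -16.5))
}
lipid_bead_names <- c("NC3", "PO4", "GL1", "GL2",
                      "C1A", "C2A", "C3A", "C4A", "C1B", "C2B", "C3B", "C4B")

#' Build the synthetic bilayer + gateway structure
#'
#' Two flat leaflets of 12-bead pseudo-POPC on a jittered square grid
#' (chain `L`), plus a pseudo-protein gateway loop (chain `P`, residues
#' 564-592) as a ring of backbone (`BB`) and side-chain (`SC1`) beads
#' hovering above the upper leaflet. Deterministic given the spec seed.
#'
#' @param spec synthetic_spec.
#' @return structure3d with box.
#' @export
build_bilayer <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$n_lipids / 2
  side <- ceiling(sqrt(m))
  a <- spec$box_xy / side
  gx <- ((seq_len(m) - 1) %% side + 0.5) * a
  gy <- ((seq_len(m) - 1) %/% side + 0.5) * a
  jit <- matrix(stats::runif(2 * m, -0.5, 0.5), ncol = 2)
  tmpl <- lipid_template()
  zP <- spec$leaflet_gap / 2
  atoms <- list(); xyz <- list()
  for (leaf in c("upper", "lower")) {
    sgn <- if (leaf == "upper") 1 else -1
    for (i in seq_len(m)) {
      resno <- if (leaf == "upper") i else m + i
      px <- gx[i] + jit[i, 1]; py <- gy[i] + jit[i, 2]
      # template z offsets are outward-positive; flip for the lower leaflet
      co <- cbind(px + tmpl[, 1], py + tmpl[, 2], sgn * (zP + tmpl[, 3]))
      atoms[[length(atoms) + 1L]] <- data.frame(
        name = lipid_bead_names, resno = resno, resname = "POPC",
        chain = "L", stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- co
    }
  }
  seq_codes <- spec$gateway_sequence
  resnos <- as.integer(names(seq_codes))
  ctr <- spec$box_xy / 2
  ring_r <- min(12, spec$box_xy / 2 - 4)
  z_loop <- zP + 28
  for (k in seq_along(resnos)) {
    th <- 2 * pi * (k - 1) / length(resnos)
    bb <- c(ctr + ring_r * cos(th), ctr + ring_r * sin(th),
            z_loop + 0.15 * (k - 1))
    code <- seq_codes[k]
    res3 <- bio3d::aa123(code)
    nm <- "BB"; co <- rbind(bb)
    if (code != "G") {
      sc <- c(ctr + (ring_r + 3) * cos(th), ctr + (ring_r + 3) * sin(th),
              bb[3])
      nm <- c(nm, "SC1"); co <- rbind(co, sc)
    }
    atoms[[length(atoms) + 1L]] <- data.frame(
      name = nm, resno = resnos[k], resname = res3, chain = "P",
      stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- co
  }
  structure3d(do.call(rbind, atoms), do.call(rbind, xyz),
              box = c(spec$box_xy, spec$box_xy, 2 * (zP + 40)))
}

# Greedy pick of n upper-leaflet lipids nearest the box centre, each at
# least min_sep apart laterally. Returns positions into lip$ids.
pick_dedicated <- function(structure, lip, n, min_sep = 10) {
  if (n == 0L) return(integer(0))
  ctr <- structure$box[1] / 2
  up <- which(structure$xyz[lip$phosphate, 3] > 0)
  xy <- structure$xyz[lip$phosphate[up], 1:2, drop = FALSE]
  ord <- up[order((xy[, 1] - ctr)^2 + (xy[, 2] - ctr)^2)]
  picked <- integer(0)
  for (i in ord) {
    if (length(picked) == n) break
    pos <- structure$xyz[lip$phosphate[i], 1:2]
    ok <- all(vapply(picked, function(j) {
      sum((structure$xyz[lip$phosphate[j], 1:2] - pos)^2) >= min_sep^2
    }, logical(1)))
    if (ok) picked <- c(picked, i)
  }
  if (length(picked) < n)
    stop("bilayer too small to host ", n, " separated planted lipids")
  picked
}

#' Simulate a synthetic trajectory with ground truth
#'
#' Emits per-frame coordinates (base geometry plus Gaussian noise) with
#' every planted event realised exactly: on a contact frame the residue's
#' side-chain bead sits 5.0 A from the designated lipid's target moiety
#' and 8.5 A from its counter-moiety; on non-contact frames the bead is
#' tens of Angstrom away, so contact labels are decidable for any noise
#' level. The extracted lipid follows the lift schedule with its phosphate
#' held exactly at the scheduled height; mound lipids are placed exactly at
#' their planted heights in a tight lateral cluster. Ground truth records
#' every Bernoulli draw, the leaflet labels, the extracted lipid and its
#' true heights.
#'
#' @param spec synthetic_spec.
#' @return list of class `synthetic_sim`: `trajectory` (trajectory3d),
#'   `truth` (list: `seed`, `n_frames`, `lipid_ids`, `leaflet`,
#'   `extracted_lipid`, `true_dz`, `contacts` — named `"resno:moiety"`
#'   0/1 vectors — `planted`, `dedicated`).
#' @export
simulate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base <- build_bilayer(spec)   # seeds the RNG with spec$seed
  lip <- lipid_index(base)
  at <- base$atoms
  np <- nrow(at); F <- spec$n_frames
  coords <- array(stats::rnorm(np * 3 * F, 0, spec$noise_sigma),
                  c(np, 3L, F)) + as.vector(base$xyz)
  zP <- spec$leaflet_gap / 2
  sc_of <- function(resno) {
    i <- which(at$chain == "P" & at$resno == resno & at$name == "SC1")
    if (!length(i)) stop("no side-chain bead for residue ", resno)
    i
  }
  # dedicated lipid assignment: extracted first, then one per planted row,
  # then the mound members
  n_occ <- if (is.null(spec$planted_occupancies)) 0L else
    nrow(spec$planted_occupancies)
  has_ext <- !is.null(spec$lift_schedule)
  ded <- pick_dedicated(base, lip, has_ext + n_occ + spec$mound_size)
  ext_i <- if (has_ext) ded[1] else NA_integer_
  occ_i <- if (n_occ) ded[has_ext + seq_len(n_occ)] else integer(0)
  mound_i <- if (spec$mound_size)
    ded[has_ext + n_occ + seq_len(spec$mound_size)] else integer(0)

  contacts <- list()
  # deterministic geometry of one planted contact on frames `on`
  plant_contact <- function(resno, moiety, lip_pos, on, dz_on = NULL) {
    if (!length(on)) return(invisible(NULL))
    nc3 <- lip$choline[lip_pos]; po4 <- lip$phosphate[lip_pos]
    bx <- base$xyz[po4, 1]; by <- base$xyz[po4, 2]
    lift <- if (is.null(dz_on)) rep(0, length(on)) else dz_on
    if (moiety == "phosphate") {
      tz <- zP + lift           # target: PO4 at its (lifted) plane height
      coords[po4, 1, on] <<- bx; coords[po4, 2, on] <<- by
      coords[po4, 3, on] <<- tz
      coords[nc3, 1, on] <<- bx; coords[nc3, 2, on] <<- by
      coords[nc3, 3, on] <<- tz - 3.5      # counter-moiety at 8.5 A
      scz <- tz + 5
    } else {
      tz <- zP + 3.5 + lift     # target: NC3
      coords[nc3, 1, on] <<- bx; coords[nc3, 2, on] <<- by
      coords[nc3, 3, on] <<- tz
      coords[po4, 1, on] <<- bx; coords[po4, 2, on] <<- by
      coords[po4, 3, on] <<- tz - 3.5      # keeps PO4 at zP + lift
      scz <- tz + 5
    }
    s <- sc_of(resno)
    coords[s, 1, on] <<- bx; coords[s, 2, on] <<- by
    coords[s, 3, on] <<- scz
    invisible(NULL)
  }

  # Bernoulli occupancy schedules
  if (n_occ) {
    po <- spec$planted_occupancies
    draw_mat <- matrix(0L, F, n_occ)
    for (r in seq_len(n_occ))
      draw_mat[, r] <- stats::rbinom(F, 1L, po$p[r])
    # a residue's side-chain bead cannot satisfy two different lipids at once
    by_res <- split(seq_len(n_occ), po$resno)
    for (g in by_res) {
      if (length(g) > 1L) {
        clash <- which(rowSums(draw_mat[, g, drop = FALSE]) > 1L)
        if (length(clash))
          stop("unsatisfiable simultaneous planted contacts for residue ",
               po$resno[g[1]], " at frame ", clash[1])
      }
    }
    for (r in seq_len(n_occ)) {
      on <- which(draw_mat[, r] == 1L)
      plant_contact(po$resno[r], po$moiety[r], occ_i[r], on)
      contacts[[paste0(po$resno[r], ":", po$moiety[r])]] <- draw_mat[, r]
    }
  }

  # extracted lipid: rigid lift with exact phosphate height
  true_dz <- NULL
  if (has_ext) {
    dz <- numeric(F)
    for (r in seq_len(nrow(spec$lift_schedule))) {
      w <- spec$lift_schedule$from[r]:spec$lift_schedule$to[r]
      dz[w] <- spec$lift_schedule$dz[r]
    }
    true_dz <- dz
    idx <- lip$particles[[ext_i]]
    for (p in idx)
      coords[p, 3, ] <- coords[p, 3, ] + dz
    po4 <- lip$phosphate[ext_i]
    coords[po4, 1, ] <- base$xyz[po4, 1]
    coords[po4, 2, ] <- base$xyz[po4, 2]
    coords[po4, 3, ] <- zP + dz
    if (!is.null(spec$contact_schedule)) {
      cs <- spec$contact_schedule
      for (r in seq_len(nrow(cs))) {
        on <- cs$from[r]:cs$to[r]
        plant_contact(cs$resno[r], cs$moiety[r], ext_i, on, dz_on = dz[on])
        ind <- integer(F); ind[on] <- 1L
        key <- paste0(cs$resno[r], ":", cs$moiety[r])
        contacts[[key]] <- if (is.null(contacts[[key]])) ind else
          pmax(contacts[[key]], ind)
      }
    }
  }

  # mound: exact static placement in a tight ring at the box centre
  if (spec$mound_size) {
    ctr <- spec$box_xy / 2
    for (j in seq_along(mound_i)) {
      th <- 2 * pi * (j - 1) / spec$mound_size
      target <- c(ctr + 4 * cos(th), ctr + 4 * sin(th),
                  zP + spec$mound_heights[j])
      idx <- lip$particles[[mound_i[j]]]
      rel <- sweep(base$xyz[idx, , drop = FALSE], 2L,
                   base$xyz[lip$phosphate[mound_i[j]], ])
      pos <- sweep(rel, 2L, target, "+")
      for (d in 1:3) coords[idx, d, ] <- pos[, d]
    }
  }

  # in-leaflet phosphates: exact plane height would be unrealistic, keep
  # their noise; the plane estimate therefore fluctuates by
  # sigma / sqrt(n_upper) and planted heights are recovered to that level
  leaflet <- ifelse(base$xyz[lip$phosphate, 3] > 0, "upper", "lower")
  traj <- trajectory3d(base, coords,
                       times = (seq_len(F) - 1) * spec$frame_stride_ns,
                       box = matrix(base$box, 1))
  truth <- list(seed = spec$seed, n_frames = F, lipid_ids = lip$ids,
                leaflet = stats::setNames(leaflet, lip$ids),
                extracted_lipid = if (has_ext) lip$ids[ext_i] else NULL,
                true_dz = true_dz, contacts = contacts,
                planted = spec$planted_occupancies,
                dedicated = lip$ids[ded])
  structure(list(trajectory = traj, truth = truth, spec = spec),
            class = "synthetic_sim")
}

#' @export
print.synthetic_sim <- function(x, ...) {
  cat("synthetic_sim:", x$spec$n_lipids, "lipids,", x$spec$n_frames,
      "frames, seed", x$spec$seed, "\n")
  if (!is.null(x$truth$extracted_lipid))
    cat("  extracted lipid:", x$truth$extracted_lipid, "\n")
  if (length(x$truth$contacts))
    cat("  planted contact schedules:",
        paste(names(x$truth$contacts), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read ground truth as JSON
#'
#' @param truth the `truth` element of a [simulate_trajectory()] result.
#' @param path file path.
#' @return `write_truth()` the path invisibly; `read_truth()` the truth
#'   list.
#' @export
write_truth <- function(truth, path) {
  if (is.null(truth) || !length(truth)) stop("empty truth object")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
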