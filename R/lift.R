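# Quantifying lipid extraction: the 6-bin lift histogram over 10-16 A,
# membrane-mound detection by single-linkage clustering of lifted lipids,
# and tracking of the single extracted lipid.

# Resolve a lipid selection to integer positions in lipids$ids.
# `selection`: NULL (dynamic: near the protein centroid), "all", character
# ids, or integer positions. Returns an n_lipids x n_frames logical matrix.
resolve_selection <- function(traj, lipids, selection, lateral_radius_A = 15) {
  nl <- length(lipids$ids)
  nf <- n_frames(traj)
  if (is.null(selection)) {
    prot <- setdiff(seq_len(n_particles(traj)), unlist(lipids$particles))
    if (!length(prot))
      stop("no protein particles for the default lateral selection; ",
           "pass an explicit selection")
    sel <- matrix(FALSE, nl, nf)
    for (k in seq_len(nf)) {
      co <- traj$coords[, , k]
      ctr <- colMeans(co[prot, 1:2, drop = FALSE])
      dxy <- co[lipids$phosphate, 1:2, drop = FALSE]
      sel[, k] <- sqrt((dxy[, 1] - ctr[1])^2 + (dxy[, 2] - ctr[2])^2) <=
        lateral_radius_A
    }
    return(sel)
  }
  idx <- if (identical(selection, "all")) seq_len(nl)
  else if (is.character(selection)) {
    i <- match(selection, lipids$ids)
    if (anyNA(i)) stop("unknown lipid id(s): ",
                       paste(selection[is.na(i)], collapse = ", "))
    i
  } else as.integer(selection)
  if (!length(idx)) stop("empty lipid selection")
  sel <- matrix(FALSE, nl, nf)
  sel[idx, ] <- TRUE
  sel
}

#' Lipid lift histogram
#'
#' Counts lipids per 1 Angstrom bin of height above the upper-leaflet
#' phosphorus plane, over the six half-open bins \[10,11), ..., \[15,16).
#' A lipid with delta-z exactly 16 is outside the range. Counts are
#' aggregated over the frame window; the per-frame breakdown is kept.
#'
#' @param traj trajectory3d.
#' @param lipids lipid_index (computed from the topology when omitted).
#' @param selection lipids to count: `NULL` (default) selects, per frame,
#'   lipids whose phosphate lies within `lateral_radius_A` of the protein
#'   centroid in x/y; `"all"`; or a vector of lipid ids / positions.
#' @param frames integer frame indices (default: all).
#' @param lateral_radius_A lateral radius for the default selection
#'   (default 15 A).
#' @param exclusion_height_A reference-plane trim (see [reference_plane()]).
#' @return object of class `lift_histogram`: list with `breaks`
#'   (10:16), `counts` (length 6), `per_frame` (6 x n_frames matrix),
#'   `n_frames`.
#' @export
lift_histogram <- function(traj, lipids = NULL, selection = NULL,
                           frames = NULL, lateral_radius_A = 15,
                           exclusion_height_A = 10) {
  if (is.null(lipids)) lipids <- lipid_index(traj)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (!length(frames)) stop("empty frame window")
  hm <- height_matrix(traj, lipids, exclusion_height_A)
  sel <- resolve_selection(traj, lipids, selection, lateral_radius_A)
  breaks <- 10:16
  per_frame <- vapply(frames, function(k) {
    dz <- hm$dz[sel[, k], k]
    dz <- dz[dz >= 10 & dz < 16]
    tabulate(findInterval(dz, breaks), nbins = 6L)  # [k, k+1) bins
  }, integer(6))
  per_frame <- matrix(per_frame, nrow = 6L,
                      dimnames = list(paste0("[", 10:15, ",", 11:16, ")"),
                                      NULL))
  structure(list(breaks = breaks, counts = rowSums(per_frame),
                 per_frame = per_frame, n_frames = length(frames),
                 frames = frames),
            class = "lift_histogram")
}

#' @export
print.lift_histogram <- function(x, ...) {
  cat("lift_histogram over", x$n_frames, "frames (counts per 1 A bin):\n")
  print(x$counts)
  invisible(x)
}

#' Detect a membrane mound in one frame
#'
#' Lipids lifted at least `min_height_A` above the phosphorus plane are
#' clustered by single linkage on their x/y phosphate positions at
#' `lateral_radius_A`; the largest cluster with at least `min_size` members
#' is reported, or `NULL` when none qualifies (absence is a valid result).
#'
#' @param traj trajectory3d.
#' @param frame frame index.
#' @param lipids lipid_index.
#' @param min_height_A lift threshold (default 10 A).
#' @param lateral_radius_A single-linkage cut distance (default 10 A).
#' @param min_size minimum cluster size (default 3).
#' @param exclusion_height_A reference-plane trim.
#' @return `NULL` or a list of class `mound_record`: `frame`, `members`
#'   (lipid ids), `size`, `mean_height`.
#' @export
detect_mound <- function(traj, frame, lipids = NULL, min_height_A = 10,
                         lateral_radius_A = 10, min_size = 3,
                         exclusion_height_A = 10) {
  if (is.null(lipids)) lipids <- lipid_index(traj)
  hm <- height_matrix(traj, lipids, exclusion_height_A)
  dz <- hm$dz[, frame]
  lifted <- which(dz >= min_height_A)
  if (!length(lifted)) return(NULL)
  if (length(lifted) == 1L) {
    cl <- 1L
  } else {
    xy <- traj$coords[lipids$phosphate[lifted], 1:2, frame, drop = FALSE]
    xy <- matrix(xy, ncol = 2L)
    hc <- stats::hclust(stats::dist(xy), method = "single")
    cl <- stats::cutree(hc, h = lateral_radius_A)
  }
  sizes <- table(cl)
  best <- as.integer(names(sizes)[which.max(sizes)])
  if (max(sizes) < min_size) return(NULL)
  members <- lifted[cl == best]
  structure(list(frame = frame, members = lipids$ids[members],
                 size = length(members), mean_height = mean(dz[members])),
            class = "mound_record")
}

#' @export
print.mound_record <- function(x, ...) {
  cat(sprintf("mound_record: frame %d, %d lipids, mean height %.2f A\n",
              x$frame, x$size, x$mean_height))
  invisible(x)
}

#' Track the single extracted lipid
#'
#' Selects the lipid spending the greatest number of window frames at
#' delta-z >= `min_height_A` (ties broken by larger mean delta-z) and
#' records its per-frame height and, when a gateway set is supplied, its
#' nearest gateway residue (minimum particle-pair distance) per frame.
#' Returns `NULL` when no lipid ever exceeds the threshold — the behaviour
#' expected of a flat, extraction-free membrane.
#'
#' @param traj trajectory3d.
#' @param gateway optional residue_set of gateway residues.
#' @param lipids lipid_index.
#' @param min_height_A lift threshold (default 10 A).
#' @param frames frame window (default: all frames).
#' @param exclusion_height_A reference-plane trim.
#' @return `NULL` or a list of class `extraction_trace`: `lipid_id`,
#'   `frames`, `dz` (per-frame heights), `nearest_residue` (data.frame or
#'   NULL), `n_lifted_frames`.
#' @export
track_extracted <- function(traj, gateway = NULL, lipids = NULL,
                            min_height_A = 10, frames = NULL,
                            exclusion_height_A = 10) {
  if (is.null(lipids)) lipids <- lipid_index(traj)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  hm <- height_matrix(traj, lipids, exclusion_height_A)
  dzw <- hm$dz[, frames, drop = FALSE]
  n_lift <- rowSums(dzw >= min_height_A)
  if (max(n_lift) == 0L) return(NULL)
  cand <- which(n_lift == max(n_lift))
  if (length(cand) > 1L) cand <- cand[which.max(rowMeans(dzw[cand, ,
                                                             drop = FALSE]))]
  nearest <- NULL
  if (!is.null(gateway)) {
    at <- traj$topology$atoms
    gw <- as.data.frame(gateway)
    gw_idx <- lapply(seq_len(nrow(gw)), function(i)
      which(at$chain == gw$chain[i] & at$resno == gw$resno[i]))
    if (any(!lengths(gw_idx)))
      stop("gateway residue(s) absent from structure: ",
           paste(gw$resno[!lengths(gw_idx)], collapse = ", "))
    lip_idx <- lipids$particles[[cand]]
    nearest <- do.call(rbind, lapply(frames, function(k) {
      co <- traj$coords[, , k]
      d <- vapply(gw_idx, function(idx)
        min_pair_dist(co[lip_idx, , drop = FALSE], co[idx, , drop = FALSE]),
        numeric(1))
      j <- which.min(d)
      data.frame(frame = k, chain = gw$chain[j], resno = gw$resno[j],
                 distance = d[j])
    }))
  }
  structure(list(lipid_id = lipids$ids[cand], frames = frames,
                 dz = dzw[cand, ], nearest_residue = nearest,
                 n_lifted_frames = max(n_lift)),
            class = "extraction_trace")
}

#' @export
print.extraction_trace <- function(x, ...) {
  cat(sprintf(
    "extraction_trace: lipid %s lifted in %d/%d frames (max dz %.1f A)\n",
    x$lipid_id, x$n_lifted_frames, length(x$frames), max(x$dz)))
  invisible(x)
}
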