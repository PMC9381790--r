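# Template-based model building: alignment mapping with insertion removal,
# backbone threading, least-clash rotamer side-chain placement, and
# conformational C-alpha metrics.
#
# The procedure mirrors standard manual homology practice for closely
# related ABC transporters: align target to template, drop target residues
# with no template counterpart, copy the template backbone verbatim,
# keep identical side chains, and rebuild substituted side chains by
# choosing the rotamer that clashes least with the rest of the model.

#' Read a two-sequence alignment from aligned FASTA
#'
#' @param path aligned-FASTA file with exactly two sequences of equal
#'   length (gaps as `-`).
#' @return list with `target` and `template` aligned strings (first and
#'   second record) and `ids`.
#' @export
read_alignment <- function(path) {
  aln <- bio3d::read.fasta(path)
  if (nrow(aln$ali) != 2L)
    stop("alignment must contain exactly 2 sequences, found ", nrow(aln$ali))
  list(target = paste(aln$ali[1, ], collapse = ""),
       template = paste(aln$ali[2, ], collapse = ""),
       ids = aln$id)
}

#' Map an alignment onto residue numbering
#'
#' Walks the alignment columns: columns with residues in both rows become
#' (target, template) residue pairs; target-only columns are recorded as
#' dropped target insertions (removed from the model, as insertions with no
#' template counterpart cannot be threaded); template-only columns are
#' skipped.
#'
#' @param target,template aligned sequences (equal length, `-` gaps).
#' @param target_numbering,template_numbering residue numbers of the
#'   non-gap positions of each sequence (default `1..n`).
#' @return object of class `alignment_map`: list with `pairs` (data.frame
#'   `target_resno`, `template_resno`, `target_code`, `template_code`),
#'   `dropped_target_insertions` (integer vector), and recomputed
#'   `identity` / `similarity` fractions over aligned pairs (similarity
#'   counts pairs within the same residue class).
#' @export
map_alignment <- function(target, template, target_numbering = NULL,
                          template_numbering = NULL) {
  tgt <- strsplit(toupper(target), "")[[1]]
  tpl <- strsplit(toupper(template), "")[[1]]
  if (length(tgt) != length(tpl))
    stop("aligned sequences differ in length (", length(tgt), " vs ",
         length(tpl), ")")
  gap <- function(x) x %in% c("-", ".")
  tgt_n <- sum(!gap(tgt)); tpl_n <- sum(!gap(tpl))
  target_numbering <- target_numbering %||% seq_len(tgt_n)
  template_numbering <- template_numbering %||% seq_len(tpl_n)
  if (length(target_numbering) != tgt_n || length(template_numbering) != tpl_n)
    stop("numbering length must match non-gap residue count")
  ti <- cumsum(!gap(tgt)); pi_ <- cumsum(!gap(tpl))
  both <- !gap(tgt) & !gap(tpl)
  pairs <- data.frame(target_resno = target_numbering[ti[both]],
                      template_resno = template_numbering[pi_[both]],
                      target_code = tgt[both], template_code = tpl[both],
                      stringsAsFactors = FALSE)
  dropped <- target_numbering[ti[!gap(tgt) & gap(tpl)]]
  scheme <- default_class_scheme()
  known <- pairs$target_code %in% names(scheme) &
    pairs$template_code %in% names(scheme)
  ident <- mean(pairs$target_code == pairs$template_code)
  simil <- mean(pairs$target_code == pairs$template_code |
                  (known & scheme[pairs$target_code] ==
                     scheme[pairs$template_code]))
  structure(list(pairs = pairs,
                 dropped_target_insertions = as.integer(dropped),
                 identity = ident, similarity = simil),
            class = "alignment_map")
}

#' @export
print.alignment_map <- function(x, ...) {
  cat(sprintf(
    "alignment_map: %d pairs, %d dropped target insertions, %.0f%% identical, %.0f%% similar\n",
    nrow(x$pairs), length(x$dropped_target_insertions), 100 * x$identity,
    100 * x$similarity))
  invisible(x)
}

aa_backbone <- c("N", "CA", "C", "O")

#' Thread a target sequence onto a template backbone
#'
#' Copies the template backbone verbatim for every aligned pair,
#' renumbering to target numbering. Aligned residues with identical amino
#' acids keep the full template side chain; substitutions keep backbone
#' only and are flagged for side-chain placement. Target insertions dropped
#' from the alignment are omitted from the model and listed. Aligned
#' C-alpha positions are bitwise identical to the template.
#'
#' @param template structure3d of the template (all-atom, or coarse-grained
#'   with `BB` backbone beads — CG residues cannot receive rebuilt side
#'   chains).
#' @param amap alignment_map. `target_code`/`template_code` columns define
#'   identity vs substitution.
#' @param chain template chain to thread (default: chain of the first
#'   particle).
#' @return object of class `threaded_model`: list with `structure`
#'   (target-numbered), `substitutions` (data.frame `resno`, `from`, `to`),
#'   `dropped_target_insertions`, `clash_report` (filled by
#'   [place_side_chains()]).
#' @export
thread_backbone <- function(template, amap, chain = NULL) {
  stopifnot(inherits(template, "structure3d"), inherits(amap, "alignment_map"))
  at <- template$atoms
  chain <- chain %||% at$chain[1]
  keep_rows <- integer(0)
  new_resno <- integer(0)
  new_resname <- character(0)
  subs <- list()
  for (i in seq_len(nrow(amap$pairs))) {
    p <- amap$pairs[i, ]
    idx <- which(at$chain == chain & at$resno == p$template_resno)
    if (!length(idx))
      stop("template residue ", chain, ":", p$template_resno,
           " absent from structure")
    bb <- idx[at$name[idx] %in% c(aa_backbone, "BB")]
    if (!length(bb))
      stop("template residue ", chain, ":", p$template_resno,
           " lacks backbone particles")
    identical_aa <- p$target_code == p$template_code
    rows <- if (identical_aa) idx else bb
    if (!identical_aa)
      subs[[length(subs) + 1L]] <- data.frame(resno = p$target_resno,
                                              from = p$template_code,
                                              to = p$target_code,
                                              stringsAsFactors = FALSE)
    keep_rows <- c(keep_rows, rows)
    new_resno <- c(new_resno, rep(p$target_resno, length(rows)))
    code3 <- bio3d::aa123(p$target_code)
    new_resname <- c(new_resname, rep(code3, length(rows)))
  }
  atoms <- data.frame(name = at$name[keep_rows], resno = new_resno,
                      resname = new_resname, chain = chain,
                      stringsAsFactors = FALSE)
  st <- structure3d(atoms, template$xyz[keep_rows, , drop = FALSE],
                    box = template$box)
  structure(list(structure = st,
                 substitutions = if (length(subs)) do.call(rbind, subs) else
                   data.frame(resno = integer(0), from = character(0),
                              to = character(0)),
                 dropped_target_insertions = amap$dropped_target_insertions,
                 clash_report = NULL),
            class = "threaded_model")
}

#' @export
print.threaded_model <- function(x, ...) {
  cat("threaded_model:", nrow(x$structure$atoms), "particles,",
      nrow(x$substitutions), "substitutions",
      if (!is.null(x$clash_report)) "(side chains placed)" else
        "(side chains pending)", "\n")
  invisible(x)
}

# Count heavy-atom clashes of candidate side-chain atoms against all model
# atoms excluding the placed residue itself.
count_clashes <- function(model_xyz, exclude_rows, cand_xyz, cutoff) {
  other <- model_xyz[-exclude_rows, , drop = FALSE]
  if (!nrow(other) || is.null(cand_xyz)) return(0L)
  sum(pairwise_dist2(cand_xyz, other) < cutoff^2)
}

#' Place one substituted side chain by least clash
#'
#' Builds every library rotamer of the target residue type on the threaded
#' backbone and counts heavy-atom clashes (pairs closer than
#' `clash_cutoff_A` between a candidate side-chain atom and any model atom
#' outside the placed residue). The candidate with the fewest clashes wins;
#' ties go to the earlier library entry.
#'
#' @param model threaded_model.
#' @param resno target residue number (must be flagged as substitution).
#' @param library rotamer library (see [default_rotamer_library()]).
#' @param clash_cutoff_A steric overlap threshold, Angstrom (default 2.5).
#' @return list of class `rotamer_choice`: `resno`, `to`, `chi`, `atoms`
#'   (matrix of placed side-chain atoms), `clash_count`, `n_candidates`.
#' @export
place_side_chain <- function(model, resno, library = default_rotamer_library(),
                             clash_cutoff_A = 2.5) {
  stopifnot(inherits(model, "threaded_model"))
  sub <- model$substitutions[model$substitutions$resno == resno, ]
  if (!nrow(sub)) stop("residue ", resno, " is not a flagged substitution")
  st <- model$structure
  at <- st$atoms
  idx <- which(at$resno == resno)
  need <- c("N", "CA", "C")
  bb <- vapply(need, function(nm) {
    j <- idx[at$name[idx] == nm]
    if (!length(j)) stop("residue ", resno, " lacks backbone atom ", nm,
                         " (coarse-grained backbones cannot host rotamers)")
    j[1]
  }, integer(1))
  type3 <- bio3d::aa123(sub$to[1])
  cands <- library[[type3]]
  if (is.null(cands) || !length(cands))
    stop("rotamer library has no candidates for ", type3)
  best <- NULL
  for (ci in seq_along(cands)) {
    sc <- build_side_chain(type3, cands[[ci]], st$xyz[bb["N"], ],
                           st$xyz[bb["CA"], ], st$xyz[bb["C"], ])
    n_clash <- count_clashes(st$xyz, idx, sc, clash_cutoff_A)
    if (is.null(best) || n_clash < best$clash_count) {
      best <- list(resno = resno, to = sub$to[1], chi = cands[[ci]],
                   atoms = sc, clash_count = n_clash,
                   n_candidates = length(cands))
    }
  }
  class(best) <- "rotamer_choice"
  best
}

#' Place all substituted side chains
#'
#' Applies [place_side_chain()] to every flagged substitution in ascending
#' residue order, updating the model after each placement so later
#' placements see earlier ones. Fills the model's clash report.
#'
#' @param model threaded_model.
#' @inheritParams place_side_chain
#' @return the model with side chains placed and `clash_report` set
#'   (data.frame: `resno`, `to`, `chi`, `clash_count`, `n_candidates`).
#' @export
place_side_chains <- function(model, library = default_rotamer_library(),
                              clash_cutoff_A = 2.5) {
  stopifnot(inherits(model, "threaded_model"))
  report <- list()
  for (resno in sort(model$substitutions$resno)) {
    choice <- place_side_chain(model, resno, library, clash_cutoff_A)
    st <- model$structure
    if (!is.null(choice$atoms)) {
      at <- st$atoms
      last <- max(which(at$resno == resno))
      n_new <- nrow(choice$atoms)
      new_atoms <- data.frame(name = rownames(choice$atoms),
                              resno = resno,
                              resname = at$resname[last],
                              chain = at$chain[last],
                              stringsAsFactors = FALSE)
      atoms <- rbind(at[seq_len(last), c("name", "resno", "resname", "chain")],
                     new_atoms,
                     if (last < nrow(at))
                       at[(last + 1):nrow(at),
                          c("name", "resno", "resname", "chain")])
      xyz <- rbind(st$xyz[seq_len(last), , drop = FALSE], choice$atoms,
                   if (last < nrow(st$xyz))
                     st$xyz[(last + 1):nrow(st$xyz), , drop = FALSE])
      model$structure <- structure3d(atoms, xyz, box = st$box)
    }
    report[[length(report) + 1L]] <- data.frame(
      resno = choice$resno, to = choice$to,
      chi = paste(round(choice$chi), collapse = ","),
      clash_count = choice$clash_count,
      n_candidates = choice$n_candidates, stringsAsFactors = FALSE)
  }
  model$clash_report <- if (length(report)) do.call(rbind, report) else
    data.frame(resno = integer(0), to = character(0), chi = character(0),
               clash_count = integer(0), n_candidates = integer(0))
  model
}

#' Write a clash report as TSV
#' @param model threaded_model with side chains placed.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clash_report <- function(model, path) {
  if (is.null(model$clash_report)) stop("side chains not placed yet")
  utils::write.table(model$clash_report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' C-alpha distance between two residues
#'
#' Euclidean distance between the C-alpha atoms (or `BB` backbone beads) of
#' two residues — the aperture metric used to compare conformations, e.g.
#' the I74-to-I371 separation across the annulus orifice.
#'
#' @param structure structure3d or threaded_model.
#' @param res_a,res_b residue numbers.
#' @param chain chain label (default: first particle's chain).
#' @return distance, Angstrom.
#' @export
ca_distance <- function(structure, res_a, res_b, chain = NULL) {
  if (inherits(structure, "threaded_model")) structure <- structure$structure
  at <- structure$atoms
  chain <- chain %||% at$chain[1]
  pick <- function(resno) {
    idx <- which(at$chain == chain & at$resno == resno &
                   at$name %in% c("CA", "BB"))
    if (!length(idx)) stop("residue ", chain, ":", resno,
                           " has no C-alpha/backbone particle")
    structure$xyz[idx[1], ]
  }
  sqrt(sum((pick(res_a) - pick(res_b))^2))
}

#' Signed aperture change between two models
#'
#' `ca_distance(model_b) - ca_distance(model_a)` for one residue pair;
#' positive when the pair moves apart in `model_b`.
#'
#' @param model_a,model_b structure3d or threaded_model objects.
#' @param residue_pair integer length-2 residue numbers.
#' @param chain chain label.
#' @return signed delta, Angstrom.
#' @export
aperture_change <- function(model_a, model_b, residue_pair, chain = NULL) {
  stopifnot(length(residue_pair) == 2L)
  ca_distance(model_b, residue_pair[1], residue_pair[2], chain) -
    ca_distance(model_a, residue_pair[1], residue_pair[2], chain)
}
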