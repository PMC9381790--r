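# Structural domains: residue sets, the residue-class scheme, proximity
# derivation, and censuses.
#
# The scientific objects here are the charged "gateway" loop of an ABC
# transporter's first extracellular domain, the "annulus" ring of
# tunnel-lining residues within 10 A of the gateway, and the small annulus
# orifice at its centre. The sets ship as presets with author numbering;
# derive_proximity_domain() recomputes the annulus from coordinates when a
# tunnel-lining set is supplied.

#' Construct a residue set
#'
#' A named set of (chain, residue number) pairs with set semantics
#' (duplicates removed).
#'
#' @param resno integer vector of residue numbers, or a compact range string
#'   accepted by [parse_ranges()].
#' @param chain chain label(s), recycled to the length of `resno`.
#' @param name optional label for the set.
#' @return object of class `residue_set`: a data.frame with columns
#'   `chain`, `resno`.
#' @export
residue_set <- function(resno, chain = "A", name = "") {
  if (is.character(resno) && length(resno) == 1L) resno <- parse_ranges(resno)
  resno <- as.integer(resno)
  df <- unique(data.frame(chain = rep_len(as.character(chain), length(resno)),
                          resno = resno, stringsAsFactors = FALSE))
  df <- df[order(df$chain, df$resno), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("residue_set", "data.frame"), set_name = name)
}

#' @export
print.residue_set <- function(x, ...) {
  cat("residue_set", if (nzchar(attr(x, "set_name") %||% ""))
    paste0("'", attr(x, "set_name"), "'") else "",
    ":", nrow(x), "residues\n")
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("  ...\n")
  invisible(x)
}

#' Size of the union of two residue sets
#'
#' @param a,b residue_set objects.
#' @return integer, `|a U b|`.
#' @examples
#' union_size(residue_set("564-592"), residue_set("69;71-80;363;368-379"))
#' @export
union_size <- function(a, b) {
  nrow(unique(rbind(as.data.frame(a)[, c("chain", "resno")],
                    as.data.frame(b)[, c("chain", "resno")])))
}

#' Default residue-class scheme
#'
#' Maps the 20 standard one-letter amino-acid codes to the seven classes
#' used for domain composition figures: basic (K, R), acidic (D, E),
#' aromatic (F, W, Y), hydrophobic (A, V, L, I, M, C), proline, glycine,
#' and neutral (S, T, N, Q, H). Histidine is counted as neutral, not basic.
#'
#' @return named character vector, code -> class.
#' @export
default_class_scheme <- function() {
  c(K = "basic", R = "basic",
    D = "acidic", E = "acidic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", M = "hydrophobic", C = "hydrophobic",
    P = "proline", G = "glycine",
    S = "neutral", T = "neutral", N = "neutral", Q = "neutral",
    H = "neutral")
}

residue_classes <- c("basic", "acidic", "aromatic", "hydrophobic",
                     "proline", "glycine", "neutral")

#' Classify one residue
#'
#' @param code one-letter amino-acid code (vectorised).
#' @param scheme named code -> class vector; see [default_class_scheme()].
#' @return character class per code.
#' @export
classify_residue <- function(code, scheme = default_class_scheme()) {
  code <- toupper(code)
  bad <- setdiff(unique(code), names(scheme))
  if (length(bad))
    stop("nonstandard amino-acid code(s): ", paste(bad, collapse = ", "))
  unname(scheme[code])
}

#' Class census of a residue set
#'
#' Counts set members per residue class. The counts always partition the
#' set: their sum equals the number of residues.
#'
#' @param set residue_set.
#' @param sequence named character vector mapping residue number (names) to
#'   one-letter code, or a data.frame with columns `chain`, `resno`, `code`.
#' @param scheme residue-class scheme.
#' @return named integer vector over all classes (zeros included), with the
#'   per-residue classification in attribute `"residues"`.
#' @export
residue_census <- function(set, sequence, scheme = default_class_scheme()) {
  set <- as.data.frame(set)
  if (nrow(set) == 0L) {
    out <- stats::setNames(integer(length(residue_classes)), residue_classes)
    return(out)
  }
  if (is.data.frame(sequence)) {
    key <- paste(sequence$chain, sequence$resno)
    codes <- stats::setNames(sequence$code, key)
    lookup <- paste(set$chain, set$resno)
  } else {
    codes <- sequence
    lookup <- as.character(set$resno)
  }
  miss <- lookup[!(lookup %in% names(codes))]
  if (length(miss))
    stop("no sequence code for residue(s): ", paste(miss, collapse = ", "))
  cl <- classify_residue(codes[lookup], scheme)
  out <- table(factor(cl, levels = residue_classes))
  out <- stats::setNames(as.integer(out), residue_classes)
  attr(out, "residues") <- data.frame(chain = set$chain, resno = set$resno,
                                      code = unname(codes[lookup]),
                                      class = cl, stringsAsFactors = FALSE)
  out
}

#' Derive a proximity-defined domain
#'
#' Returns every candidate residue having at least one particle within
#' `cutoff` of any particle of any source residue. With the gateway as
#' source and the tunnel-lining residues as candidates and the default
#' 10 A cutoff this reproduces the annulus definition. All particles of a
#' residue participate (not only C-alpha). Monotone in `cutoff`.
#'
#' @param structure structure3d.
#' @param source residue_set of source residues.
#' @param candidates residue_set of candidate residues.
#' @param cutoff_A distance cutoff, Angstrom (default 10).
#' @return residue_set of qualifying candidates.
#' @export
derive_proximity_domain <- function(structure, source, candidates,
                                    cutoff_A = 10) {
  stopifnot(inherits(structure, "structure3d"), cutoff_A > 0)
  at <- structure$atoms
  idx_of <- function(set, what) {
    set <- as.data.frame(set)
    lapply(seq_len(nrow(set)), function(i) {
      idx <- which(at$chain == set$chain[i] & at$resno == set$resno[i])
      if (!length(idx))
        stop("cannot resolve ", what, " residue ", set$chain[i], ":",
             set$resno[i], " in structure")
      idx
    })
  }
  src_idx <- unlist(idx_of(source, "source"))
  cand_list <- idx_of(candidates, "candidate")
  src_xyz <- structure$xyz[src_idx, , drop = FALSE]
  keep <- vapply(cand_list, function(idx) {
    min_pair_dist(structure$xyz[idx, , drop = FALSE], src_xyz) <= cutoff_A
  }, logical(1))
  cd <- as.data.frame(candidates)[keep, , drop = FALSE]
  residue_set(cd$resno, cd$chain, name = "proximity_domain")
}

#' Census of basic residues inside a membrane slab
#'
#' Counts residues, per class, that have at least one particle with z inside
#' `[z_lower, z_upper]` — the intramembrane census used to contrast ABCA1's
#' charge-free transmembrane midsection with lipid floppases. Residue codes
#' are taken from 3-letter residue names in the structure; non-amino-acid
#' residues (lipids, water, ions) are ignored.
#'
#' @param structure structure3d.
#' @param z_lower,z_upper slab bounds, Angstrom, `z_lower <= z_upper`.
#' @param scheme residue-class scheme.
#' @return named integer vector of class counts; attribute `"residues"`
#'   lists the (chain, resno, code, class) of every residue in the slab and
#'   attribute `"basic_residues"` the basic subset.
#' @export
intramembrane_basic_census <- function(structure, z_lower, z_upper,
                                       scheme = default_class_scheme()) {
  stopifnot(inherits(structure, "structure3d"))
  if (z_lower > z_upper) stop("slab bounds must be ordered")
  at <- structure$atoms
  code3 <- toupper(at$resname)
  code1 <- suppressWarnings(bio3d::aa321(code3))
  is_aa <- !is.na(code1) & code1 != "X"
  inz <- structure$xyz[, 3] >= z_lower & structure$xyz[, 3] <= z_upper
  sel <- is_aa & inz
  empty <- stats::setNames(integer(length(residue_classes)), residue_classes)
  if (!any(sel)) {
    attr(empty, "residues") <- data.frame(chain = character(0),
                                          resno = integer(0),
                                          code = character(0),
                                          class = character(0))
    attr(empty, "basic_residues") <- attr(empty, "residues")
    return(empty)
  }
  res <- unique(data.frame(chain = at$chain[sel], resno = at$resno[sel],
                           code = code1[sel], stringsAsFactors = FALSE))
  res$class <- classify_residue(res$code, scheme)
  out <- table(factor(res$class, levels = residue_classes))
  out <- stats::setNames(as.integer(out), residue_classes)
  attr(out, "residues") <- res
  attr(out, "basic_residues") <- res[res$class == "basic", , drop = FALSE]
  out
}

#' Domain presets for the ABCA1 gateway/annulus complex
#'
#' Residue sets with author numbering: the 29-residue gateway loop
#' (564-592), the annulus (69, 71-80, 363, 368-379), the 11 charged gateway
#' residues, and the annulus orifice. The source literature states the
#' orifice membership two ways, so both are shipped: `orifice_figure`
#' (73-75, 77, 78, 371, 375) and `orifice_text` (73, 74, 77, 371, 375);
#' neither is promoted as canonical.
#'
#' @param chain chain label applied to all sets (default `"A"`).
#' @return named list of residue_set objects: `gateway`, `annulus`,
#'   `charged_gateway`, `orifice_figure`, `orifice_text`.
#' @export
abca1_domains <- function(chain = "A") {
  list(
    gateway = residue_set("564-592", chain, name = "gateway"),
    annulus = residue_set("69;71-80;363;368-379", chain, name = "annulus"),
    charged_gateway = residue_set(c(564, 565, 568, 570, 571, 575, 579, 581,
                                    584, 585, 587),
                                  chain, name = "charged_gateway"),
    orifice_figure = residue_set("73-75;77;78;371;375", chain,
                                 name = "orifice_figure"),
    orifice_text = residue_set("73-74;77;371;375", chain,
                               name = "orifice_text"))
}

#' Read / write residue sets as TSV
#'
#' Two-column tab-separated files with header `chain`, `resno`.
#'
#' @param path file path.
#' @param set residue_set to write.
#' @param name label for the set on read.
#' @return `read_residue_set()` a residue_set; `write_residue_set()` the
#'   path, invisibly.
#' @export
read_residue_set <- function(path, name = "") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain", "resno") %in% names(df)))
    stop("residue-set TSV needs columns 'chain' and 'resno': ", path)
  residue_set(df$resno, df$chain, name = name)
}

#' @rdname read_residue_set
#' @export
write_residue_set <- function(set, path) {
  utils::write.table(as.data.frame(set)[, c("chain", "resno")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
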