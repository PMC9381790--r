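# Internal geometry and parsing helpers shared across modules.

# Squared Euclidean distances between rows of A (m x 3) and B (n x 3).
pairwise_dist2 <- function(A, B) {
  A <- matrix(A, ncol = 3L)
  B <- matrix(B, ncol = 3L)
  a2 <- rowSums(A * A)
  b2 <- rowSums(B * B)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard against negative round-off
  d2
}

# Minimum Euclidean distance between two point sets.
min_pair_dist <- function(A, B) sqrt(min(pairwise_dist2(A, B)))

#' Parse a compact residue-range string
#'
#' Expands strings such as `"564-592;69;71-80"` into an integer vector of
#' residue numbers. Segments are separated by `;` or `,`; each segment is a
#' single number or an inclusive `lo-hi` range.
#'
#' @param x character scalar with ranges.
#' @return sorted integer vector of unique residue numbers.
#' @examples
#' parse_ranges("564-592;69;71-80")
#' @export
parse_ranges <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, "[;,]")[[1]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(integer(0))
  out <- lapply(parts, function(p) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (ab[1] > ab[2]) stop("descending range: ", p, call. = FALSE)
      seq.int(ab[1], ab[2])
    } else if (grepl("^[0-9]+$", p)) {
      as.integer(p)
    } else {
      stop("cannot parse range segment: '", p, "'", call. = FALSE)
    }
  })
  sort(unique(unlist(out)))
}

# FNV-1a 32-bit hash of a character scalar, returned as 8-hex-digit string.
# Used to stamp report files with a config fingerprint; deterministic and
# dependency-free.
fnv1a_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
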