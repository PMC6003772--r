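#' The RNA alphabet
#'
#' The four ribonucleotide bases, in the fixed order used throughout the
#' package. All sequences are handled in RNA sense (`U`, never `T`); readers
#' normalise `T` to `U` on input.
#'
#' @return Character vector `c("A", "C", "G", "U")`.
#' @export
rna_bases <- function() c("A", "C", "G", "U")

#' Enumerate the 64 triplets
#'
#' All trinucleotide sequences over the RNA alphabet, in lexicographic order.
#' This is the substrate space of a random (`pppNNN`) triplet pool.
#'
#' @return Character vector of length 64.
#' @examples
#' length(all_triplets())
#' @export
all_triplets <- function() {
  b <- rna_bases()
  g <- expand.grid(p3 = b, p2 = b, p1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$p1, g$p2, g$p3))
}

#' Reverse complement of RNA sequences
#'
#' @param x Character vector of RNA sequences (`A`, `C`, `G`, `U`).
#' @return Character vector of the same length, each entry the reverse
#'   complement of the input read 5'->3'.
#' @examples
#' rna_revcomp("GGU") # the cognate product of template GGU is ACC
#' @export
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Geometric mean
#'
#' Computed in log space. Non-positive values are replaced by `floor` first;
#' if any value is still non-positive the result is 0 (with a warning), the
#' limiting value of the geometric mean.
#'
#' @param x Numeric vector, values >= 0.
#' @param floor Replacement for non-positive entries before averaging
#'   (default 0, i.e. no flooring).
#' @return A single number.
#' @examples
#' geometric_mean(c(0.75, 2 / 3, 0.5)) # 0.25^(1/3)
#' @export
geometric_mean <- function(x, floor = 0) {
  if (length(x) == 0L) abort("geometric_mean() needs at least one value.")
  if (anyNA(x)) abort("geometric_mean() does not accept missing values.")
  if (any(x < 0)) abort("geometric_mean() needs non-negative values.")
  x[x <= 0] <- floor
  if (any(x <= 0)) {
    warn("zero values present and no positive floor: geometric mean is 0.")
    return(0)
  }
  exp(mean(log(x)))
}

# Hamming distance between equal-length strings, vectorised over x.
hamming <- function(x, y) {
  xs <- strsplit(x, "", fixed = TRUE)
  ys <- strsplit(y, "", fixed = TRUE)[[1]]
  vapply(xs, function(s) sum(s != ys), integer(1))
}

# Split sequences into a character matrix (reads x positions); all sequences
# must share one length.
seq_matrix <- function(seqs) {
  n <- unique(nchar(seqs))
  if (length(n) != 1L) abort("sequences must share one length.")
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = length(seqs), ncol = n, byrow = TRUE)
}

# Substitute bases at `hit` cells of a base character vector, uniformly over
# the three alternatives. Assumes the RNG is already seeded by the caller.
substitute_bases <- function(bases, hit) {
  if (!any(hit)) return(bases)
  b <- rna_bases()
  cur <- match(bases[hit], b)
  bases[hit] <- b[(cur - 1L + sample.int(3L, sum(hit), replace = TRUE)) %% 4L + 1L]
  bases
}
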