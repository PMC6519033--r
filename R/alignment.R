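#' Haplotype alignment at segregating sites
#'
#' Container for `n` phased haplotypes observed at the `S` biallelic
#' segregating sites of a sequence of total length `length_bp`. Alleles are
#' coded 0/1 per site; coordinates are 0-based and half-open throughout the
#' package. Monomorphic columns are removed on construction, so every column
#' carries both alleles.
#'
#' @param mat integer matrix, haplotypes in rows, segregating sites in
#'   columns, entries 0/1.
#' @param positions 0-based bp positions of the columns, strictly
#'   increasing, all in `[0, length_bp)`.
#' @param length_bp total sequence length in bp.
#' @return An object of class `hap_alignment` with elements `mat`,
#'   `positions`, `length_bp`, `n`, `S`.
#' @examples
#' aln <- hap_alignment(rbind(c(0, 0), c(0, 1), c(1, 1)), c(10, 40), 100)
#' aln$S
#' @export
hap_alignment <- function(mat, positions, length_bp) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  mat <- matrix(as.integer(mat), nrow = nrow(mat))
  positions <- as.numeric(positions)
  if (ncol(mat) != length(positions))
    stop("number of columns must match number of positions")
  if (length(positions) && (is.unsorted(positions, strictly = TRUE)))
    stop("positions must be strictly increasing")
  if (length(positions) && (min(positions) < 0 || max(positions) >= length_bp))
    stop("positions must lie in [0, length_bp)")
  if (length(mat) && !all(mat %in% c(0L, 1L)))
    stop("allele codes must be 0/1")
  # drop monomorphic columns so invariants hold
  if (ncol(mat)) {
    cs <- colSums(mat)
    keep <- cs > 0L & cs < nrow(mat)
    mat <- mat[, keep, drop = FALSE]
    positions <- positions[keep]
  }
  structure(
    list(mat = mat, positions = positions, length_bp = as.numeric(length_bp),
         n = nrow(mat), S = ncol(mat)),
    class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("hap_alignment: %d haplotypes, %d segregating sites, %g bp\n",
              x$n, x$S, x$length_bp))
  invisible(x)
}

#' Restrict an alignment to a window
#'
#' Subsets the columns falling in the half-open window `[start, end)` and
#' rebases positions to window-local coordinates. Used by the pipeline to
#' form per-segment alignments.
#'
#' @param aln a [hap_alignment].
#' @param start,end window boundaries in bp, 0-based half-open.
#' @return A `hap_alignment` of length `end - start`.
#' @export
window_alignment <- function(aln, start, end) {
  stopifnot(inherits(aln, "hap_alignment"), end > start,
            start >= 0, end <= aln$length_bp)
  keep <- aln$positions >= start & aln$positions < end
  hap_alignment(aln$mat[, keep, drop = FALSE],
                aln$positions[keep] - start, end - start)
}
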