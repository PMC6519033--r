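#' Read a haplotype alignment from FASTA
#'
#' One record per haplotype, equal lengths. Sequences are case-folded;
#' biallelic segregating sites are extracted (sites with more than two
#' alleles are reduced to the two most frequent; sites containing `N` or
#' gaps in any haplotype are dropped, with a message giving the count).
#'
#' @param path FASTA file.
#' @return A [hap_alignment]; allele 0 is the major allele at each site.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2) stop("need at least 2 FASTA records")
  if (length(unique(Biostrings::width(seqs))) != 1)
    stop("ragged FASTA: records have unequal lengths")
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate FASTA record ids")
  chars <- toupper(as.matrix(seqs))
  alignment_from_chars(chars, ncol(chars))
}

# build a hap_alignment from an n x L character matrix of nucleotides
alignment_from_chars <- function(chars, L, positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(chars)) - 1
  ok_allele <- chars %in% c("A", "C", "G", "T")
  dim(ok_allele) <- dim(chars)
  clean <- colSums(!ok_allele) == 0
  n_dropped <- sum(!clean)
  if (n_dropped) message(sprintf("dropped %d site(s) with N/gap characters",
                                 n_dropped))
  chars <- chars[, clean, drop = FALSE]
  positions <- positions[clean]
  cols <- lapply(seq_len(ncol(chars)), function(j) {
    tab <- sort(table(chars[, j]), decreasing = TRUE)
    if (length(tab) < 2) return(NULL)
    top2 <- names(tab)[1:2]
    x <- chars[, j]
    keep <- x %in% top2            # haplotypes carrying a rarer 3rd allele
    if (!all(keep)) return(NULL)   # at this site: treat site as unusable
    as.integer(x == top2[2])
  })
  use <- !vapply(cols, is.null, logical(1))
  mat <- if (any(use)) do.call(cbind, cols[use]) else
    matrix(0L, nrow(chars), 0)
  hap_alignment(mat, positions[use], L)
}

#' Write a haplotype alignment as FASTA
#'
#' Renders the 0/1 allele matrix as nucleotides: each segregating site
#' gets a reference/alternative base pair and monomorphic positions are
#' filled with a seeded random background sequence, so the file
#' round-trips through [read_fasta_alignment] to the same alignment.
#'
#' @param aln a [hap_alignment].
#' @param path output file.
#' @param seed seed for the background sequence and allele assignment.
#' @export
write_fasta_alignment <- function(aln, path, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  L <- as.integer(aln$length_bp)
  bases <- c("A", "C", "G", "T")
  background <- sample(bases, L, replace = TRUE)
  ref <- background[aln$positions + 1L]
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  con <- file(path, "w"); on.exit(close(con), add = TRUE)
  for (i in seq_len(aln$n)) {
    s <- background
    s[aln$positions + 1L] <- ifelse(aln$mat[i, ] == 1L, alt, ref)
    writeLines(c(sprintf(">hap_%d", i), paste(s, collapse = "")), con)
  }
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Keeps biallelic SNP records with phased genotypes and expands each
#' diploid sample into two haplotypes. Positions are converted from the
#' VCF's 1-based coordinates to region-local 0-based ones.
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param region `c(start, end)` half-open 0-based region on the single
#'   contig; defaults to `[0, max position + 1)`.
#' @param samples optional character vector of sample names to keep.
#' @param allow_unphased phase unphased genotypes at random (seeded)
#'   instead of failing.
#' @param seed seed for random phasing.
#' @return A [hap_alignment].
#' @export
read_phased_vcf <- function(path, region = NULL, samples = NULL,
                            allow_unphased = FALSE, seed = 1) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  pos1 <- as.numeric(fix[, "POS"])
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (any(!biallelic))
    message(sprintf("dropped %d non-biallelic-SNP record(s)", sum(!biallelic)))
  gt <- vcfR::extract.gt(v)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(gt))
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    gt <- gt[, samples, drop = FALSE]
  }
  if (is.null(region)) region <- c(0, max(pos1))
  keep <- biallelic & pos1 - 1 >= region[1] & pos1 - 1 < region[2]
  gt <- gt[keep, , drop = FALSE]
  pos0 <- pos1[keep] - 1 - region[1]
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    if (!allow_unphased)
      stop(sprintf("%d unphased genotype(s); set allow_unphased = TRUE to phase at random",
                   sum(unphased)))
    message(sprintf("randomly phasing %d unphased genotype(s)", sum(unphased)))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  hap_rows <- lapply(seq_len(ncol(gt)), function(s) {
    al <- strsplit(gsub("/", "|", gt[, s]), "|", fixed = TRUE)
    a1 <- as.integer(vapply(al, `[`, character(1), 1))
    a2 <- as.integer(vapply(al, `[`, character(1), 2))
    flip <- unphased[, s] & stats::runif(length(a1)) < 0.5
    rbind(ifelse(flip, a2, a1), ifelse(flip, a1, a2))
  })
  mat <- do.call(rbind, hap_rows)
  if (anyNA(mat)) stop("missing genotypes are not supported")
  hap_alignment(mat, pos0, region[2] - region[1])
}

#' Write / read a recombination map as BED-like text
#'
#' Four tab-separated columns: `chrom`, `start`, `end`, `rho_per_bp`,
#' half-open 0-based intervals tiling `[0, L)`. The round trip preserves
#' breakpoints and rates at full precision.
#'
#' @param map a [recomb_map].
#' @param path file path.
#' @param chrom chromosome label to write.
#' @export
write_map_bed <- function(map, path, chrom = "seq") {
  bounds <- c(0, map$breakpoints, map$length_bp)
  df <- data.frame(chrom = chrom,
                   start = format(bounds[-length(bounds)], digits = 17),
                   end = format(bounds[-1], digits = 17),
                   rho = format(map$rates, digits = 17))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_bed
#' @export
read_map_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "rho"))
  if (!nrow(df)) stop("empty map file")
  o <- order(df$start)
  df <- df[o, , drop = FALSE]
  if (any(df$start[-1] != df$end[-nrow(df)]))
    stop("map intervals must tile the sequence without gaps or overlaps")
  if (df$start[1] != 0) stop("map must start at 0")
  recomb_map(df$end[nrow(df)], df$start[-1], df$rho)
}
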