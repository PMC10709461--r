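#' Per-gene haplotype alignment
#'
#' The central container for sequence data: a character matrix of aligned
#' haplotypes (rows) by alignment columns, with each diploid sample
#' contributing exactly two rows and every row assigned to one of two
#' species. `frame_offset` gives the 0-based column of the first complete
#' codon, so codon-aware site classification can be applied downstream.
#'
#' Characters are normalised to upper case `A C G T N -`; anything else
#' becomes `N`. Gaps (`-`) are treated as missing data by all statistics.
#'
#' @param gene_id single gene identifier.
#' @param seqs character matrix (rows = haplotypes, columns = positions),
#'   or a character vector of equal-length sequence strings.
#' @param sample_ids sample identifier per diploid sample; each sample owns
#'   two consecutive rows (haplotypes 1 and 2).
#' @param species species label per sample (length = number of samples) or
#'   per row (length = number of rows).
#' @param frame_offset integer 0..2, position of the first complete codon.
#' @return an object of class `hap_alignment`.
#' @export
hap_alignment <- function(gene_id, seqs, sample_ids, species, frame_offset = 0L) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- unique(nchar(seqs))
    if (length(lens) != 1L)
      stop("gene ", gene_id, ": sequences differ in length")
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  stopifnot(is.matrix(seqs))
  seqs <- toupper(seqs)
  seqs[!seqs %in% c("A", "C", "G", "T", "-")] <- "N"
  n_row <- nrow(seqs)
  if (n_row != 2L * length(sample_ids))
    stop("gene ", gene_id, ": expected 2 rows per sample (",
         length(sample_ids), " samples, ", n_row, " rows)")
  if (length(species) == length(sample_ids))
    species <- rep(species, each = 2L)
  if (length(species) != n_row)
    stop("gene ", gene_id, ": species labels do not match rows")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  rownames(seqs) <- paste0(rep(sample_ids, each = 2L), "_h", 1:2)
  structure(
    list(gene_id = gene_id, seqs = seqs,
         sample_ids = as.character(sample_ids),
         species = as.character(species),
         frame_offset = as.integer(frame_offset)),
    class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat("<hap_alignment> gene", x$gene_id, "-", nrow(x$seqs), "haplotypes x",
      ncol(x$seqs), "columns;", "species:",
      paste(sprintf("%s (%d)", names(table(x$species)), table(x$species)),
            collapse = ", "),
      "; frame offset", x$frame_offset, "\n")
  invisible(x)
}

#' @export
dim.hap_alignment <- function(x) dim(x$seqs)

# rows of a given species
species_rows <- function(aln, sp) which(aln$species == sp)

species_names <- function(aln) unique(aln$species)

# integer-encoded alignment: 1..4 for A,C,G,T, NA for N/-
encode_alignment <- function(seqs) {
  m <- match(seqs, c("A", "C", "G", "T"))
  dim(m) <- dim(seqs)
  rownames(m) <- rownames(seqs)
  m
}
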