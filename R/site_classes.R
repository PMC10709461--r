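# Codon-aware site classification.
#
# Fourfold-degenerate third positions are the closest thing a CDS offers to
# neutrally evolving sites; the first two codon positions are the least
# neutral. Classification is per alignment column and requires unanimity:
# a third position counts as fourfold only if every row without missing
# data in that codon carries a first-two-base context from a
# fourfold-degenerate family of the standard nuclear code.

# families of the standard genetic code whose third position is fourfold
# degenerate, keyed by the first two codon bases
FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "GT", "GC", "GG", "AC")

#' Classify alignment columns into codon-based site classes
#'
#' Produces boolean masks for the three site classes used throughout the
#' pipeline: `all` (every column), `fourfold` (third codon positions whose
#' codon context is fourfold degenerate in every non-missing row) and
#' `first_two` (positions 1-2 of complete codons). Columns of incomplete
#' terminal codons belong to class `all` only. A polymorphic first or
#' second position that moves any row out of the fourfold family
#' disqualifies the site.
#'
#' @param aln a [hap_alignment]; its `frame_offset` locates codon 1.
#' @return object of class `site_class_mask`: list with `gene_id` and
#'   `masks` (named list of logical vectors over columns).
#' @export
classify_codon_sites <- function(aln) {
  stopifnot(inherits(aln, "hap_alignment"))
  L <- ncol(aln$seqs)
  off <- aln$frame_offset
  if (off >= L) stop("frame_offset ", off, " >= alignment length ", L)
  n_codons <- (L - off) %/% 3L
  if (n_codons < 1L) stop("gene ", aln$gene_id, ": no complete codon")
  fourfold <- logical(L)
  first_two <- logical(L)
  for (cdn in seq_len(n_codons)) {
    c1 <- off + 3L * (cdn - 1L) + 1L           # 1-based first column
    first_two[c(c1, c1 + 1L)] <- TRUE
    codon <- aln$seqs[, c1:(c1 + 2L), drop = FALSE]
    ok <- rowSums(codon == "N" | codon == "-") == 0L
    if (!any(ok)) next
    pref <- paste0(codon[ok, 1L], codon[ok, 2L])
    if (all(pref %in% FOURFOLD_PREFIXES)) fourfold[c1 + 2L] <- TRUE
  }
  structure(list(gene_id = aln$gene_id,
                 masks = list(all = rep(TRUE, L),
                              fourfold = fourfold,
                              first_two = first_two)),
            class = "site_class_mask")
}

#' @export
print.site_class_mask <- function(x, ...) {
  cat("<site_class_mask>", x$gene_id, "-",
      paste(sprintf("%s: %d", names(x$masks),
                    vapply(x$masks, sum, 0L)), collapse = ", "), "\n")
  invisible(x)
}

#' Complete-deletion column filter
#'
#' Restricts a site-class mask (or any column subset) to columns where no
#' haplotype row carries missing data (`N` or `-`), the within-gene
#' treatment used for all per-gene statistics.
#'
#' @param aln a [hap_alignment].
#' @param mask logical vector over columns, column indices, or `NULL`
#'   (all columns).
#' @return integer vector of retained column indices, with attribute
#'   `n_in` (columns considered).
#' @export
complete_deletion_filter <- function(aln, mask = NULL) {
  complete <- colSums(aln$seqs == "N" | aln$seqs == "-") == 0L
  cols <- if (is.null(mask)) seq_len(ncol(aln$seqs))
          else if (is.logical(mask)) which(mask) else as.integer(mask)
  keep <- cols[complete[cols]]
  attr(keep, "n_in") <- length(cols)
  keep
}

#' Export site-class masks as a BED-like table
#'
#' One row per maximal run of same-class columns, 0-based half-open
#' intervals.
#'
#' @param masks list of `site_class_mask` objects.
#' @param path optional TSV output path.
#' @return data frame `gene_id`, `start`, `end`, `class`.
#' @export
export_site_classes <- function(masks, path = NULL) {
  rows <- lapply(masks, function(m) {
    do.call(rbind, lapply(c("fourfold", "first_two"), function(cl) {
      v <- m$masks[[cl]]
      if (!any(v)) return(NULL)
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      data.frame(gene_id = m$gene_id, start = starts[r$values],
                 end = ends[r$values], class = cl,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
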