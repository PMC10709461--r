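#' Read per-gene haplotype alignments from FASTA
#'
#' Accepts either a single multi-FASTA or a directory of `.fa`/`.fasta`
#' files. Sequence headers follow the `gene|sample|haplotype` convention
#' used by [write_gene_alignments()] (haplotype is 1 or 2). All sequences
#' of a gene must share one length; lower-case bases are upper-cased and
#' unknown characters become `N`.
#'
#' @param path multi-FASTA file or directory containing FASTA files.
#' @param species_map data frame with columns `sample_id` and `species`
#'   covering every sample in the input.
#' @param frame_offsets optional named integer vector (gene -> offset 0..2);
#'   defaults to 0 for every gene.
#' @return named list of [hap_alignment] objects, one per gene.
#' @export
read_gene_alignments <- function(path, species_map, frame_offsets = NULL) {
  stopifnot(all(c("sample_id", "species") %in% names(species_map)))
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  } else path
  seqs <- do.call(c, lapply(files, function(f)
    Biostrings::readBStringSet(f)))
  hdr <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(hdr) != 3L
  if (any(bad))
    stop("FASTA headers must be 'gene|sample|haplotype'; offending: ",
         names(seqs)[which(bad)[1]])
  gene <- vapply(hdr, `[[`, "", 1L)
  samp <- vapply(hdr, `[[`, "", 2L)
  miss <- setdiff(unique(samp), species_map$sample_id)
  if (length(miss))
    stop("samples missing from species_map: ", paste(miss, collapse = ", "))
  sp_of <- setNames(as.character(species_map$species), species_map$sample_id)
  out <- lapply(split(seq_along(seqs), gene), function(idx) {
    g <- gene[idx[1]]
    lens <- unique(Biostrings::width(seqs[idx]))
    if (length(lens) != 1L)
      stop("gene ", g, ": sequences differ in length (",
           paste(lens, collapse = ", "), ")")
    # keep haplotype pairs adjacent and in stable sample order
    ord <- idx[order(samp[idx], names(seqs)[idx])]
    mat <- do.call(rbind, strsplit(as.character(seqs[ord]), ""))
    sids <- unique(samp[ord])
    hap_alignment(g, mat, sids, sp_of[sids],
                  frame_offset = unname(frame_offsets[g] %||% 0L))
  })
  out[order(names(out))]
}

#' Write haplotype alignments as multi-FASTA
#'
#' Emits headers in the `gene|sample|haplotype` convention read back by
#' [read_gene_alignments()].
#'
#' @param alns list of [hap_alignment] objects.
#' @param path output file.
#' @export
write_gene_alignments <- function(alns, path) {
  recs <- do.call(c, unname(lapply(alns, function(a) {
    s <- apply(a$seqs, 1L, paste, collapse = "")
    names(s) <- paste(a$gene_id, rep(a$sample_ids, each = 2L), 1:2, sep = "|")
    s
  })))
  Biostrings::writeXStringSet(Biostrings::BStringSet(recs), path, width = 80L)
  invisible(path)
}

#' Extract the species map of an alignment set
#' @param alns list of [hap_alignment] objects.
#' @return data frame with `sample_id`, `species`.
#' @export
alignment_species_map <- function(alns) {
  a <- alns[[1]]
  data.frame(sample_id = a$sample_ids,
             species = a$species[seq(1L, length(a$species), by = 2L)],
             stringsAsFactors = FALSE)
}

#' Convert a multi-sample VCF to pseudo-haplotype alignments
#'
#' Rebuilds per-gene alignments from diploid genotypes against reference
#' CDS sequences: each sample becomes two rows; homozygous genotypes copy
#' the allele to both rows, heterozygous genotypes are split according to
#' `phasing` (`"random"` assigns the two alleles to the two rows in random
#' order under `seed`; `"ref_alt_split"` always puts REF on row 1, ALT on
#' row 2), and missing genotypes become `N` on both rows. Indels are
#' skipped and sites with more than two observed alleles are set to `N`;
#' both events are counted in the `log` attribute of the result.
#'
#' VCF `CHROM` must name the gene (matching the CDS FASTA), `POS` is the
#' 1-based position within the CDS.
#'
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param reference_cds FASTA of reference CDS sequences, or a named
#'   character vector of sequences.
#' @param species_map data frame `sample_id`, `species`.
#' @param phasing `"random"` or `"ref_alt_split"`.
#' @param seed integer seed for random phasing (recorded in the output
#'   `phasing` attribute).
#' @return named list of [hap_alignment] objects with attributes
#'   `phasing` and `log`.
#' @export
vcf_to_pseudohaplotypes <- function(vcf, reference_cds, species_map,
                                    phasing = c("random", "ref_alt_split"),
                                    seed = 1L) {
  phasing <- match.arg(phasing)
  if (is.character(reference_cds) && length(reference_cds) == 1L &&
      file.exists(reference_cds)) {
    ref <- Biostrings::readBStringSet(reference_cds)
    reference_cds <- setNames(as.character(ref), sub("\\s.*", "", names(ref)))
  }
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  miss <- setdiff(samples, species_map$sample_id)
  if (length(miss))
    stop("VCF samples missing from species_map: ", paste(miss, collapse = ", "))
  sp_of <- setNames(as.character(species_map$species), species_map$sample_id)
  rng <- local({ set.seed(seed); NULL })
  log <- c(indel_skipped = 0L, multiallelic_masked = 0L, missing_gt = 0L)

  out <- lapply(names(reference_cds), function(g) {
    refseq <- toupper(strsplit(reference_cds[[g]], "")[[1]])
    n_samp <- length(samples)
    mat <- matrix(rep(refseq, each = 2L * n_samp), nrow = 2L * n_samp)
    rows <- fix$CHROM == g
    for (r in which(rows)) {
      pos <- as.integer(fix$POS[r])
      alleles <- c(fix$REF[r], strsplit(fix$ALT[r], ",")[[1]])
      if (any(nchar(alleles) != 1L)) {            # indel
        log["indel_skipped"] <<- log["indel_skipped"] + 1L
        next
      }
      gts <- gt[r, ]
      codes <- strsplit(gsub("\\|", "/", gts), "/")
      obs <- unique(unlist(codes))
      obs <- obs[obs != "." & !is.na(obs)]
      if (length(obs) > 2L) {                     # >2 observed alleles
        log["multiallelic_masked"] <<- log["multiallelic_masked"] + 1L
        mat[, pos] <- "N"
        next
      }
      for (si in seq_len(n_samp)) {
        cd <- codes[[si]]
        ri <- c(2L * si - 1L, 2L * si)
        if (length(cd) != 2L || any(cd == ".") || any(is.na(cd))) {
          mat[ri, pos] <- "N"
          log["missing_gt"] <<- log["missing_gt"] + 1L
        } else {
          al <- alleles[as.integer(cd) + 1L]
          if (al[1] != al[2] && phasing == "random" && runif(1) < 0.5)
            al <- rev(al)
          mat[ri, pos] <- al
        }
      }
    }
    hap_alignment(g, mat, samples, sp_of[samples])
  })
  names(out) <- names(reference_cds)
  attr(out, "phasing") <- list(rule = phasing, seed = seed)
  attr(out, "log") <- log
  out
}

#' Read an FPKM expression matrix
#'
#' Expects a TSV whose first column is `gene_id` and whose remaining
#' columns are samples. Missing cells and negative values are errors (no
#' silent imputation).
#'
#' @param path TSV file.
#' @param species_map optional data frame `sample_id`, `species`; stored as
#'   the sample-to-species map of the matrix.
#' @return object of class `expression_matrix`: list with `fpkm` (genes x
#'   samples numeric matrix) and `species` (named vector sample -> species).
#' @export
read_expression <- function(path, species_map = NULL) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(d)[1] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene_id
  if (anyNA(m)) {
    w <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("missing FPKM at gene ", rownames(m)[w[1]], ", sample ",
         colnames(m)[w[2]])
  }
  if (any(m < 0)) {
    w <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative FPKM at gene ", rownames(m)[w[1]], ", sample ",
         colnames(m)[w[2]])
  }
  expression_matrix(m, species_map)
}

#' Construct an expression matrix object
#' @param fpkm numeric genes x samples matrix, non-negative.
#' @param species_map data frame `sample_id`, `species`, or named vector.
#' @export
expression_matrix <- function(fpkm, species_map = NULL) {
  stopifnot(is.matrix(fpkm), all(fpkm >= 0))
  sp <- NULL
  if (!is.null(species_map)) {
    sp <- if (is.data.frame(species_map))
      setNames(as.character(species_map$species), species_map$sample_id)
    else species_map
    miss <- setdiff(colnames(fpkm), names(sp))
    if (length(miss))
      stop("samples missing from species map: ", paste(miss, collapse = ", "))
    sp <- sp[colnames(fpkm)]
    if (length(unique(sp)) != 2L)
      stop("expression matrix needs samples from exactly two species")
  }
  structure(list(fpkm = fpkm, species = sp), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$fpkm), "genes x", ncol(x$fpkm),
      "samples\n")
  invisible(x)
}

#' Write an FPKM matrix as TSV
#' @param x `expression_matrix` or numeric matrix.
#' @param path output file.
#' @export
write_expression <- function(x, path) {
  m <- if (inherits(x, "expression_matrix")) x$fpkm else x
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the gene category table
#'
#' TSV with columns `gene_id`, `category` (one of freqA, rareA, freqX,
#' rareX), `chromosome`, `position`. Each gene appears once.
#'
#' @param path TSV file.
#' @return data frame with the four columns, `category` a factor.
#' @export
read_gene_categories <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_gene_categories(d)
}

#' @rdname read_gene_categories
#' @param categories category data frame to write.
#' @export
write_gene_categories <- function(categories, path) {
  write.table(categories, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_gene_categories <- function(d) {
  stopifnot(all(c("gene_id", "category") %in% names(d)))
  bad <- setdiff(unique(d$category), CATEGORY_LEVELS)
  if (length(bad))
    stop("unknown gene categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(d$gene_id))
    stop("duplicated gene_id in category table: ",
         d$gene_id[anyDuplicated(d$gene_id)])
  d$category <- factor(d$category, levels = CATEGORY_LEVELS)
  d
}
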