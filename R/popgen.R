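# Per-gene polymorphism and divergence statistics.
#
# All estimators operate on haplotype rows of a character matrix over
# {A,C,G,T,N,-}; columns containing missing data among the supplied rows
# are removed first (complete deletion), and every statistic reports the
# number of columns actually used via attribute "n_sites".

# drop columns with missing data among the selected rows; returns integer
# encoded sub-matrix (1..4) with attribute "cols" = retained columns
.clean_block <- function(seqs, rows, cols) {
  m <- seqs[rows, cols, drop = FALSE]
  keep <- colSums(m == "N" | m == "-") == 0L
  structure(encode_alignment(m[, keep, drop = FALSE]), cols = cols[keep])
}

# per-column mean pairwise difference (the n/(n-1)-corrected heterozygosity,
# identical to the average Hamming mismatch over all unordered row pairs)
.pi_per_column <- function(enc) {
  n <- nrow(enc)
  cnt <- vapply(1:4, function(b) colSums(enc == b), numeric(ncol(enc)))
  if (ncol(enc) == 1L) cnt <- matrix(cnt, nrow = 1L)
  (n^2 - rowSums(cnt^2)) / (n * (n - 1))
}

#' Nucleotide diversity (pi)
#'
#' Average per-site proportion of differences over all unordered pairs of
#' haplotypes, equivalent to the sample-size-corrected heterozygosity
#' `n/(n-1) * (1 - sum p_a^2)` summed over sites and divided by the number
#' of sites used.
#'
#' @param aln a [hap_alignment] or character matrix of haplotypes.
#' @param cols columns to use (indices or logical); default all.
#' @param rows haplotype rows to use; default all.
#' @return per-site diversity with attribute `n_sites`.
#' @export
nucleotide_diversity <- function(aln, cols = NULL, rows = NULL) {
  seqs <- if (inherits(aln, "hap_alignment")) aln$seqs else aln
  rows <- rows %||% seq_len(nrow(seqs))
  if (length(rows) < 2L) stop("nucleotide diversity needs >= 2 haplotypes")
  cols <- .resolve_cols(cols, ncol(seqs))
  enc <- .clean_block(seqs, rows, cols)
  if (ncol(enc) < 1L) stop("no columns left after filtering")
  structure(mean(.pi_per_column(enc)), n_sites = ncol(enc))
}

.resolve_cols <- function(cols, L) {
  if (is.null(cols)) seq_len(L) else if (is.logical(cols)) which(cols)
  else as.integer(cols)
}

#' Tajima's D
#'
#' Normalised difference between the mean-pairwise-difference and the
#' segregating-sites estimators of the population mutation rate, using the
#' standard constants a1, a2, b1, b2, c1, c2, e1, e2 for `n` sequences.
#' Undefined (NA, with attribute `reason`) when no site segregates.
#'
#' @inheritParams nucleotide_diversity
#' @return D, or `NA` when undefined; attribute `n_sites` as for
#'   [nucleotide_diversity()], attribute `S` = segregating sites.
#' @export
tajimas_d <- function(aln, cols = NULL, rows = NULL) {
  seqs <- if (inherits(aln, "hap_alignment")) aln$seqs else aln
  rows <- rows %||% seq_len(nrow(seqs))
  n <- length(rows)
  if (n < 3L) stop("Tajima's D needs >= 3 haplotypes")
  cols <- .resolve_cols(cols, ncol(seqs))
  enc <- .clean_block(seqs, rows, cols)
  pc <- .pi_per_column(enc)
  S <- sum(pc > 0)
  if (S == 0L)
    return(structure(NA_real_, n_sites = ncol(enc), S = 0L,
                     reason = "no segregating sites"))
  pi_total <- sum(pc)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  structure(D, n_sites = ncol(enc), S = S)
}

#' Between-species divergence Dxy
#'
#' Mean per-site mismatch proportion over all between-species pairs of
#' haplotypes.
#'
#' @param aln a [hap_alignment] (uses its species labels) or character
#'   matrix, in which case `rows1`/`rows2` must be given.
#' @param cols columns to use; default all.
#' @param rows1,rows2 haplotype rows of the two species (matrix input).
#' @return per-site divergence with attribute `n_sites`.
#' @export
dxy <- function(aln, cols = NULL, rows1 = NULL, rows2 = NULL) {
  b <- .two_species_block(aln, cols, rows1, rows2)
  structure(mean(.dxy_per_column(b$enc1, b$enc2)), n_sites = ncol(b$enc1))
}

.two_species_block <- function(aln, cols, rows1, rows2) {
  if (inherits(aln, "hap_alignment")) {
    sps <- species_names(aln)
    if (length(sps) != 2L) stop("alignment must contain two species")
    rows1 <- species_rows(aln, sps[1])
    rows2 <- species_rows(aln, sps[2])
    seqs <- aln$seqs
  } else seqs <- aln
  if (!length(rows1) || !length(rows2)) stop("both species need >= 1 row")
  cols <- .resolve_cols(cols, ncol(seqs))
  enc <- .clean_block(seqs, c(rows1, rows2), cols)
  if (ncol(enc) < 1L) stop("no columns left after filtering")
  list(enc1 = enc[seq_along(rows1), , drop = FALSE],
       enc2 = enc[length(rows1) + seq_along(rows2), , drop = FALSE])
}

.dxy_per_column <- function(enc1, enc2) {
  n1 <- nrow(enc1); n2 <- nrow(enc2)
  c1 <- vapply(1:4, function(b) colSums(enc1 == b), numeric(ncol(enc1)))
  c2 <- vapply(1:4, function(b) colSums(enc2 == b), numeric(ncol(enc2)))
  if (ncol(enc1) == 1L) { c1 <- matrix(c1, 1L); c2 <- matrix(c2, 1L) }
  1 - rowSums(c1 * c2) / (n1 * n2)
}

#' Interspecific differentiation Fst
#'
#' The Hudson/Nei-family estimator `1 - mean(pi_within) / pi_between`,
#' where `pi_between` is [dxy()] on the same columns and `pi_within` is the
#' unweighted mean of the two within-species diversities. Undefined (NA)
#' when `pi_between` is zero.
#'
#' @inheritParams dxy
#' @return Fst in `(-Inf, 1]` or NA; attribute `n_sites`.
#' @export
fst <- function(aln, cols = NULL, rows1 = NULL, rows2 = NULL) {
  b <- .two_species_block(aln, cols, rows1, rows2)
  if (nrow(b$enc1) < 2L || nrow(b$enc2) < 2L)
    stop("Fst needs >= 2 haplotypes per species")
  pi_b <- mean(.dxy_per_column(b$enc1, b$enc2))
  if (pi_b == 0)
    return(structure(NA_real_, n_sites = ncol(b$enc1),
                     reason = "no between-species diversity"))
  pi_w <- (mean(.pi_per_column(b$enc1)) + mean(.pi_per_column(b$enc2))) / 2
  structure(1 - pi_w / pi_b, n_sites = ncol(b$enc1))
}

#' Kelly's ZnS linkage-disequilibrium statistic
#'
#' Mean squared allelic correlation r^2 (the `D^2 / (p1 q1 p2 q2)` form,
#' computed on haplotypes) over all pairs of biallelic segregating sites.
#' Undefined (NA) with fewer than two usable sites.
#'
#' @inheritParams nucleotide_diversity
#' @return mean r^2 in `[0, 1]` or NA; attributes `n_sites` (columns used)
#'   and `n_snps` (biallelic segregating sites).
#' @export
zns <- function(aln, cols = NULL, rows = NULL) {
  seqs <- if (inherits(aln, "hap_alignment")) aln$seqs else aln
  rows <- rows %||% seq_len(nrow(seqs))
  cols <- .resolve_cols(cols, ncol(seqs))
  enc <- .clean_block(seqs, rows, cols)
  nall <- apply(enc, 2L, function(x) length(unique(x)))
  bi <- which(nall == 2L)
  if (length(bi) < 2L)
    return(structure(NA_real_, n_sites = ncol(enc), n_snps = length(bi),
                     reason = "fewer than 2 biallelic segregating sites"))
  X <- vapply(bi, function(j) as.numeric(enc[, j] == enc[1L, j]),
              numeric(nrow(enc)))
  r2 <- cor(X)^2
  structure(mean(r2[upper.tri(r2)]),
            n_sites = ncol(enc), n_snps = length(bi))
}

#' Ploidy adjustment of autosomal diversity
#'
#' X-linked genes have three quarters of the autosomal effective population
#' size, so autosome-X comparisons of pi use autosomal values scaled to 75%.
#'
#' @param pi non-negative diversity value(s).
#' @return `0.75 * pi`.
#' @export
adjust_autosomal_pi <- function(pi) {
  stopifnot(all(pi >= 0, na.rm = TRUE))
  0.75 * pi
}

#' All five statistics for one gene
#'
#' Computes each statistic on its designated site classes: pi and Tajima's
#' D per species on fourfold-degenerate and first-two-codon-position sites,
#' and Fst, Dxy and ZnS (per species) on all sites. The class sets are
#' configurable via `classes_for`.
#'
#' @param aln a [hap_alignment] with two species.
#' @param mask [classify_codon_sites()] result for the gene (computed if
#'   missing).
#' @param category gene category label (carried through).
#' @param classes_for named list assigning site classes to `pi`, `tajd`,
#'   `fst`, `dxy`, `zns`.
#' @return data frame, one row per site class, with StatRecord columns
#'   (`pi_1`, `pi_2`, `tajd_1`, `tajd_2`, `fst`, `dxy`, `zns_1`, `zns_2`,
#'   `n_sites_used`, `pi_adjusted`).
#' @export
per_gene_stats <- function(aln, mask = NULL, category = NA_character_,
                           classes_for = list(
                             pi = c("fourfold", "first_two"),
                             tajd = c("fourfold", "first_two"),
                             fst = "all", dxy = "all", zns = "all")) {
  mask <- mask %||% classify_codon_sites(aln)
  sps <- species_names(aln)
  r1 <- species_rows(aln, sps[1]); r2 <- species_rows(aln, sps[2])
  classes <- unique(unlist(classes_for))
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  rows <- lapply(classes, function(cl) {
    cc <- mask$masks[[cl]]
    used <- length(complete_deletion_filter(aln, cc))
    want <- function(stat) cl %in% classes_for[[stat]]
    data.frame(
      gene_id = aln$gene_id, category = category, site_class = cl,
      n_sites_used = used,
      pi_1 = if (want("pi")) safe(as.numeric(nucleotide_diversity(aln, cc, r1))) else NA_real_,
      pi_2 = if (want("pi")) safe(as.numeric(nucleotide_diversity(aln, cc, r2))) else NA_real_,
      tajd_1 = if (want("tajd")) safe(as.numeric(tajimas_d(aln, cc, r1))) else NA_real_,
      tajd_2 = if (want("tajd")) safe(as.numeric(tajimas_d(aln, cc, r2))) else NA_real_,
      fst = if (want("fst")) safe(as.numeric(fst(aln, cc))) else NA_real_,
      dxy = if (want("dxy")) safe(as.numeric(dxy(aln, cc))) else NA_real_,
      zns_1 = if (want("zns")) safe(as.numeric(zns(aln, cc, r1))) else NA_real_,
      zns_2 = if (want("zns")) safe(as.numeric(zns(aln, cc, r2))) else NA_real_,
      pi_adjusted = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Statistics table for a whole alignment set
#'
#' Applies [per_gene_stats()] to every gene and optionally the 75% ploidy
#' adjustment of autosomal pi (categories `freqA`, `rareA`).
#'
#' @param alns list of [hap_alignment] objects.
#' @param categories gene category table (see [read_gene_categories()]).
#' @param adjust_pi apply [adjust_autosomal_pi()] to autosomal rows.
#' @param ... passed to [per_gene_stats()].
#' @return data frame, rows = gene x site class.
#' @export
stats_table <- function(alns, categories, adjust_pi = FALSE, ...) {
  cat_of <- setNames(as.character(categories$category), categories$gene_id)
  out <- do.call(rbind, lapply(alns, function(a)
    per_gene_stats(a, category = cat_of[a$gene_id] %||% NA_character_, ...)))
  rownames(out) <- NULL
  if (adjust_pi) {
    auto <- out$category %in% c("freqA", "rareA")
    out$pi_1[auto] <- adjust_autosomal_pi(out$pi_1[auto])
    out$pi_2[auto] <- adjust_autosomal_pi(out$pi_2[auto])
    out$pi_adjusted[auto] <- TRUE
  }
  out
}

#' Genome-wide track export
#'
#' Long-format table (chromosome, position, statistic, value) for plotting
#' per-gene statistics along the genome.
#'
#' @param stats output of [stats_table()].
#' @param categories gene category table with `chromosome`, `position`.
#' @param path optional TSV output path.
#' @export
export_genome_track <- function(stats, categories, path = NULL) {
  pos <- categories[, c("gene_id", "chromosome", "position")]
  m <- merge(stats, pos, by = "gene_id")
  long <- do.call(rbind, lapply(
    c("pi_1", "pi_2", "tajd_1", "tajd_2", "fst", "dxy", "zns_1", "zns_2"),
    function(s) data.frame(chromosome = m$chromosome, position = m$position,
                           gene_id = m$gene_id, site_class = m$site_class,
                           statistic = s, value = m[[s]],
                           stringsAsFactors = FALSE)))
  long <- long[!is.na(long$value), ]
  rownames(long) <- NULL
  if (!is.null(path))
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  long
}
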