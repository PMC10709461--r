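# Joint (two-population) site-frequency spectra.
#
# A joint SFS is an (n1+1) x (n2+1) matrix whose (i, j) entry counts
# variant sites with allele count i in species 1 and j in species 2.
# The fixed corners (0,0) and (n1,n2) carry no information about
# polymorphism and are always zero. Folded spectra keep only cells at or
# below the minor-allele diagonal 2*(i+j) <= n1+n2.

#' Construct a joint SFS object
#' @param counts numeric (n1+1) x (n2+1) matrix.
#' @param n1,n2 haploid sample sizes.
#' @param folded logical.
#' @export
joint_sfs <- function(counts, n1, n2, folded = FALSE) {
  stopifnot(nrow(counts) == n1 + 1L, ncol(counts) == n2 + 1L,
            all(counts >= 0))
  counts[1L, 1L] <- 0
  counts[n1 + 1L, n2 + 1L] <- 0
  dimnames(counts) <- list(0:n1, 0:n2)
  structure(list(counts = counts, n1 = as.integer(n1), n2 = as.integer(n2),
                 folded = isTRUE(folded)),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs>", x$n1, "x", x$n2,
      if (x$folded) "(folded)" else "(unfolded)",
      "- total mass", format(sum(x$counts)), "\n")
  invisible(x)
}

#' Total number of sites in a spectrum
#' @param sfs a `joint_sfs`.
#' @export
sfs_mass <- function(sfs) sum(sfs$counts)

#' Fold a joint SFS onto the minor-allele orientation
#'
#' Adds each cell to its complement `(n1-i, n2-j)` and keeps the member of
#' the pair at or below the diagonal `2*(i+j) = n1+n2` (ties broken
#' lexicographically; self-complementary cells are left as they are).
#' Folding an already folded spectrum is the identity.
#'
#' @param sfs a `joint_sfs`.
#' @export
fold_sfs <- function(sfs) {
  if (sfs$folded) return(sfs)
  n1 <- sfs$n1; n2 <- sfs$n2
  S <- sfs$counts
  out <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in 0:n1) for (j in 0:n2) {
    ri <- n1 - i; rj <- n2 - j
    tot2 <- 2L * (i + j)
    keep <- if (tot2 < n1 + n2) TRUE
            else if (tot2 > n1 + n2) FALSE
            else if (i == ri && j == rj) NA        # self-complementary
            else (i < ri) || (i == ri && j < rj)
    if (is.na(keep)) out[i + 1L, j + 1L] <- S[i + 1L, j + 1L]
    else if (keep)
      out[i + 1L, j + 1L] <- S[i + 1L, j + 1L] + S[ri + 1L, rj + 1L]
  }
  joint_sfs(out, n1, n2, folded = TRUE)
}

#' Build a joint SFS from haplotype alignments
#'
#' Every biallelic segregating site contributes one unit of mass. Sites
#' where all rows are present contribute 1 to the cell given by the allele
#' counts in the two species; sites with missing rows are projected down to
#' `(n1, n2)` by hypergeometric expectation, and sites with fewer
#' non-missing rows than the target in either species are skipped (counted
#' in the `log` attribute, as are sites with more than two alleles).
#'
#' Allele orientation: with `ancestral` sequences the derived allele is
#' counted (unfolded spectrum possible); otherwise an arbitrary consistent
#' orientation is used and the spectrum must be folded.
#'
#' @param alns list of [hap_alignment] objects (two species).
#' @param n1,n2 target haploid sample sizes (projection size).
#' @param fold return the folded spectrum.
#' @param ancestral optional named list/vector of ancestral sequences (one
#'   string per gene) for derived-allele orientation.
#' @param per_gene also return the per-gene spectra (for bootstrapping).
#' @return a `joint_sfs`; if `per_gene`, attribute `per_gene` holds a list
#'   of per-gene count matrices.
#' @export
build_joint_sfs <- function(alns, n1 = 20L, n2 = 20L, fold = TRUE,
                            ancestral = NULL, per_gene = FALSE) {
  if (!fold && is.null(ancestral))
    stop("unfolded spectra need ancestral alleles; supply `ancestral` or fold")
  sps <- species_names(alns[[1]])
  log <- c(skipped_low_coverage = 0L, skipped_multiallelic = 0L)
  gene_mats <- lapply(alns, function(a) {
    r1 <- species_rows(a, sps[1]); r2 <- species_rows(a, sps[2])
    e1 <- encode_alignment(a$seqs[r1, , drop = FALSE])
    e2 <- encode_alignment(a$seqs[r2, , drop = FALSE])
    anc <- if (!is.null(ancestral)) {
      s <- ancestral[[a$gene_id]]
      match(toupper(strsplit(s, "")[[1]]), c("A", "C", "G", "T"))
    }
    # per-column allele counts (4 x L), vectorised over the alignment
    c1 <- t(vapply(1:4, function(b) colSums(e1 == b, na.rm = TRUE),
                   numeric(ncol(e1))))
    c2 <- t(vapply(1:4, function(b) colSums(e2 == b, na.rm = TRUE),
                   numeric(ncol(e2))))
    tot <- c1 + c2
    n_alleles <- colSums(tot > 0)
    log["skipped_multiallelic"] <<- log["skipped_multiallelic"] +
      sum(n_alleles > 2L)
    M <- matrix(0, n1 + 1L, n2 + 1L)
    for (p in which(n_alleles == 2L)) {
      obs <- which(tot[, p] > 0)
      focal <- if (!is.null(anc)) {
        if (!anc[p] %in% obs) { # ancestral allele lost: orientation unknown
          log["skipped_multiallelic"] <<- log["skipped_multiallelic"] + 1L
          next
        }
        setdiff(obs, anc[p])    # derived allele
      } else obs[1]             # arbitrary but consistent
      a1 <- sum(c1[, p]); a2 <- sum(c2[, p])
      if (a1 < n1 || a2 < n2) {
        log["skipped_low_coverage"] <<- log["skipped_low_coverage"] + 1L
        next
      }
      k1 <- c1[focal, p]
      k2 <- c2[focal, p]
      if (a1 == n1 && a2 == n2) {
        M[k1 + 1L, k2 + 1L] <- M[k1 + 1L, k2 + 1L] + 1
      } else {
        w1 <- dhyper(0:n1, k1, a1 - k1, n1)
        w2 <- dhyper(0:n2, k2, a2 - k2, n2)
        M <- M + outer(w1, w2)
      }
    }
    M
  })
  total <- Reduce(`+`, gene_mats)
  out <- joint_sfs(total, n1, n2, folded = FALSE)
  if (fold) out <- fold_sfs(out)
  attr(out, "log") <- log
  if (per_gene) attr(out, "per_gene") <- gene_mats
  out
}

#' Hypergeometric projection of a joint SFS
#'
#' Entry-wise expectation of subsampling without replacement from
#' `(n1, n2)` down to `(m1, m2)` haploid samples. Mass projected into the
#' fixed corners is absorbed (reported via attribute `corner_mass`).
#' Defined for unfolded spectra; fold afterwards if needed.
#'
#' @param sfs an unfolded `joint_sfs`.
#' @param m1,m2 target sizes, `m1 <= n1`, `m2 <= n2`.
#' @export
project_sfs <- function(sfs, m1, m2) {
  if (sfs$folded) stop("project unfolded spectra, then fold")
  if (m1 > sfs$n1 || m2 > sfs$n2) stop("projection size exceeds sample size")
  P1 <- vapply(0:sfs$n1, function(i) dhyper(0:m1, i, sfs$n1 - i, m1),
               numeric(m1 + 1L))           # (m1+1) x (n1+1)
  P2 <- vapply(0:sfs$n2, function(j) dhyper(0:m2, j, sfs$n2 - j, m2),
               numeric(m2 + 1L))
  M <- P1 %*% sfs$counts %*% t(P2)
  corner <- M[1L, 1L] + M[m1 + 1L, m2 + 1L]
  out <- joint_sfs(M, m1, m2, folded = FALSE)
  attr(out, "corner_mass") <- corner
  out
}

#' Bootstrap spectra by resampling genes
#'
#' Resamples genes with replacement and rebuilds the joint SFS for each
#' replicate; deterministic under `seed`.
#'
#' @param alns list of [hap_alignment] objects (>= 1 gene).
#' @param n_boot number of replicates (100 in the standard protocol).
#' @param seed integer seed.
#' @param ... passed to [build_joint_sfs()].
#' @return list of `joint_sfs` replicates.
#' @export
bootstrap_resample_sfs <- function(alns, n_boot = 100L, seed = 1L, ...) {
  obs <- build_joint_sfs(alns, ..., per_gene = TRUE)
  per_gene <- attr(obs, "per_gene")
  G <- length(per_gene)
  set.seed(seed)
  lapply(seq_len(n_boot), function(b) {
    idx <- sample.int(G, G, replace = TRUE)
    m <- Reduce(`+`, per_gene[idx])
    r <- joint_sfs(m, obs$n1, obs$n2, folded = FALSE)
    if (obs$folded) r <- fold_sfs(r)
    r
  })
}

#' Read / write spectra as plain text
#'
#' A one-line header `n1 n2 folded` followed by the `(n1+1) x (n2+1)`
#' matrix, rows = species-1 allele counts.
#'
#' @param sfs a `joint_sfs`.
#' @param path file path.
#' @export
write_sfs <- function(sfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(sfs$n1, sfs$n2, ifelse(sfs$folded, "folded", "unfolded")),
             con)
  write.table(sfs$counts, con, sep = " ", row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\\s+")[[1]]
  n1 <- as.integer(hdr[1]); n2 <- as.integer(hdr[2])
  m <- as.matrix(read.table(path, skip = 1L))
  dimnames(m) <- NULL
  joint_sfs(m, n1, n2, folded = hdr[3] == "folded")
}
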