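# shared fixture builders: everything is generated in code

# alignment from per-haplotype strings; samples are consecutive pairs
aln_strings <- function(strs, gene = "g1", species = NULL, frame = 0L) {
  n <- length(strs)
  stopifnot(n %% 2 == 0)
  species <- species %||% rep(c("species1", "species2"), each = n / 2 / 2)
  hap_alignment(gene, strs, sample_ids = paste0("S", seq_len(n / 2)),
                species = species, frame_offset = frame)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random two-species alignment with given dimensions
random_aln <- function(n_per_species = 3L, n_cols = 30L, gene = "g1",
                       bases = c("A", "C", "G", "T"), p_missing = 0) {
  n <- 4L * n_per_species          # two species, two rows per diploid
  m <- matrix(sample(bases, n * n_cols, replace = TRUE), nrow = n)
  if (p_missing > 0)
    m[sample(length(m), round(p_missing * length(m)))] <- "N"
  hap_alignment(gene, m, sample_ids = paste0("S", seq_len(n / 2)),
                species = rep(c("species1", "species2"), each = n / 2))
}

# brute-force mean pairwise per-site mismatch over given row index pairs
brute_pairwise <- function(seqs, pairs, cols) {
  rows <- unique(unlist(pairs))
  sub <- seqs[rows, cols, drop = FALSE]
  ok <- cols[colSums(sub == "N" | sub == "-") == 0]
  mean(vapply(pairs, function(p)
    mean(seqs[p[1], ok] != seqs[p[2], ok]), 0))
}

all_pairs <- function(idx) {
  out <- list()
  for (i in seq_along(idx)[-length(idx)])
    for (j in (i + 1):length(idx)) out[[length(out) + 1L]] <- c(idx[i], idx[j])
  out
}

cross_pairs <- function(idx1, idx2) {
  out <- list()
  for (i in idx1) for (j in idx2) out[[length(out) + 1L]] <- c(i, j)
  out
}

# letters consistent with the significance matrix: share a letter iff NOT
# significantly different
letters_consistent <- function(letters, pairwise_p, alpha) {
  g <- length(letters)
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    share <- length(intersect(strsplit(letters[i], "")[[1]],
                              strsplit(letters[j], "")[[1]])) > 0
    sig <- pairwise_p[i, j] < alpha
    if (share == sig) return(FALSE)
  }
  TRUE
}
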