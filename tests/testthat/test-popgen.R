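test_that("nucleotide diversity matches simple hand cases", {
  a <- aln_strings(rep("ACGTACGTAC", 8))
  expect_equal(as.numeric(nucleotide_diversity(a)), 0)
  two <- matrix(c(strsplit("AAAAAAAAAA", "")[[1]],
                  strsplit("AAAAAAAAAT", "")[[1]]), nrow = 2, byrow = TRUE)
  expect_equal(as.numeric(nucleotide_diversity(two)), 0.1)
  expect_error(nucleotide_diversity(two[1, , drop = FALSE]), ">= 2")
})

test_that("pi and dxy equal all-pairs brute force on random alignments", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_aln(3, 30, p_missing = ifelse(i > 10, 0.04, 0))
    r1 <- species_rows <- which(a$species == "species1")
    r2 <- which(a$species == "species2")
    pi1 <- nucleotide_diversity(a, rows = r1)
    expect_equal(as.numeric(pi1), brute_pairwise(a$seqs, all_pairs(r1), 1:30),
                 tolerance = 1e-12)
    d <- dxy(a)
    expect_equal(as.numeric(d),
                 brute_pairwise(a$seqs, cross_pairs(r1, r2), 1:30),
                 tolerance = 1e-12)
  }
})

# second implementation of Tajima's D straight from the published constants
oracle_tajd <- function(mat) {
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(x) length(unique(x)) > 1))
  if (S == 0) return(NA_real_)
  k <- mean(vapply(all_pairs(seq_len(n)), function(p)
    sum(mat[p[1], ] != mat[p[2], ]), 0))
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

test_that("Tajima's D matches an independently coded constants oracle", {
  set.seed(9)
  mat <- matrix(sample(c("A", "G"), 5 * 20, TRUE, prob = c(0.8, 0.2)),
                nrow = 5)
  expect_equal(as.numeric(tajimas_d(mat)), oracle_tajd(mat),
               tolerance = 1e-12)
  for (i in 1:10) {
    m <- matrix(sample(c("A", "C", "T"), 6 * 25, TRUE, c(.7, .2, .1)), 6)
    expect_equal(as.numeric(tajimas_d(m)), oracle_tajd(m), tolerance = 1e-12)
  }
})

test_that("Tajima's D is undefined without segregating sites and negative for singletons", {
  mono <- matrix("A", 4, 10)
  expect_true(is.na(tajimas_d(mono)))
  expect_identical(attr(tajimas_d(mono), "reason"), "no segregating sites")
  # n = 10 haplotypes, 5 singleton sites -> excess of rare variants, D < 0
  m <- matrix("C", 10, 20)
  for (s in 1:5) m[s, s] <- "T"
  expect_lt(as.numeric(tajimas_d(m)), 0)
})

test_that("dxy hand cases and species symmetry", {
  a <- aln_strings(c(rep("AAAA", 4), rep("AATT", 4)))
  expect_equal(as.numeric(dxy(a)), 0.5)
  same <- aln_strings(rep("ACGT", 8))
  expect_equal(as.numeric(dxy(same)), 0)
  # swapping species labels leaves dxy unchanged, swaps within-species pi
  set.seed(3)
  b <- random_aln(3, 40)
  b_sw <- b
  b_sw$species <- ifelse(b$species == "species1", "species2", "species1")
  expect_equal(as.numeric(dxy(b)), as.numeric(dxy(b_sw)))
  st <- per_gene_stats(b)
  st_sw <- per_gene_stats(b_sw)
  expect_equal(st$pi_1, st_sw$pi_2)
  expect_equal(st$pi_2, st_sw$pi_1)
})

test_that("Fst agrees with its defining ratio and handles degenerate cases", {
  mono_same <- aln_strings(rep("AAAA", 8))
  expect_true(is.na(fst(mono_same)))                    # 0/0
  fixed_diff <- aln_strings(c(rep("AAAA", 4), rep("TTTT", 4)))
  expect_equal(as.numeric(fst(fixed_diff)), 1)          # pi_w = 0
  set.seed(13)
  for (i in 1:10) {
    a <- random_aln(3, 25)
    r1 <- which(a$species == "species1"); r2 <- which(a$species == "species2")
    piw <- (brute_pairwise(a$seqs, all_pairs(r1), 1:25) +
            brute_pairwise(a$seqs, all_pairs(r2), 1:25)) / 2
    pib <- brute_pairwise(a$seqs, cross_pairs(r1, r2), 1:25)
    expect_equal(as.numeric(fst(a)), 1 - piw / pib, tolerance = 1e-12)
    expect_lte(as.numeric(fst(a)), 1)
  }
})

test_that("ZnS equals the pairwise r2 brute force and its invariances hold", {
  # two sites with identical row partition -> complete LD
  a <- aln_strings(c("AT", "AT", "AT", "AT", "GC", "GC", "GC", "GC"))
  expect_equal(as.numeric(zns(a)), 1)
  one_site <- aln_strings(c("A", "A", "A", "A", "T", "T", "T", "T"))
  expect_true(is.na(zns(one_site)))
  set.seed(21)
  m <- matrix(sample(c("A", "G"), 8 * 6, TRUE), nrow = 8)
  while (sum(apply(m, 2, function(x) length(unique(x)) == 2)) < 6)
    m <- matrix(sample(c("A", "G"), 8 * 6, TRUE), nrow = 8)
  # brute force over all 15 pairs from the D^2/(p1 q1 p2 q2) form
  r2s <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    pA <- mean(m[, i] == "A"); pB <- mean(m[, j] == "A")
    pAB <- mean(m[, i] == "A" & m[, j] == "A")
    r2s <- c(r2s, (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB)))
  }
  expect_equal(as.numeric(zns(m)), mean(r2s), tolerance = 1e-12)
  # row order and allele relabeling leave ZnS unchanged
  expect_equal(as.numeric(zns(m[sample(8), ])), as.numeric(zns(m)))
  relab <- m
  relab[relab == "A"] <- "x"; relab[relab == "G"] <- "A"; relab[relab == "x"] <- "T"
  expect_equal(as.numeric(zns(relab)), as.numeric(zns(m)))
})

test_that("ploidy adjustment scales pi by 0.75 and commutes with the median", {
  expect_equal(adjust_autosomal_pi(0.04), 0.03)
  expect_equal(adjust_autosomal_pi(0), 0)
  set.seed(2)
  v <- rexp(101, 50)
  expect_equal(median(adjust_autosomal_pi(v)), 0.75 * median(v))
})

test_that("per-gene statistics assemble correctly on a planted-SNP gene", {
  # 12 columns = 4 codons of GGx (fourfold at 3,6,9,12); 6 haplotype rows
  # per species would need 12 rows; use 8 rows (2 samples/species)
  base <- "GGAGGCGGAGGC"
  rows <- c("GGAGGCGGAGGC", "GGAGGCGGAGGC", "GGAGGCGGAGGT", "GGAGGCGGAGGT",
            "GGCGGCGGAGGC", "GGCGGCGGAGGC", "GGCGGCGGAGGC", "GGCGGCGGAGGC")
  a <- aln_strings(rows)
  st <- per_gene_stats(a, category = "freqA")
  ff <- st[st$site_class == "fourfold", ]
  # species1: one SNP at column 12 (freq 2/4): pi = (4/3)*(1-0.5^2-0.5^2)/4
  expect_equal(ff$pi_1, (2 * 2 * 2 / (4 * 3)) / 4)
  # species2 monomorphic
  expect_equal(ff$pi_2, 0)
  al <- st[st$site_class == "all", ]
  # dxy: columns 3 differs for all cross pairs; column 12: half
  expect_equal(al$dxy, (1 + 0.5) / 12)
  expect_true(is.na(ff$tajd_2))         # no segregating sites in species2
  mono <- aln_strings(rep(base, 8))
  stm <- per_gene_stats(mono)
  expect_equal(stm$pi_1[stm$site_class != "all"], c(0, 0),
               ignore_attr = TRUE)
  expect_true(all(is.na(stm$tajd_1)))
  expect_true(all(is.na(stm[stm$site_class == "all", c("zns_1", "zns_2")])))
})

test_that("stats_table applies the ploidy adjustment to autosomal rows only", {
  set.seed(5)
  alns <- list(g1 = random_aln(3, 36, gene = "g1"),
               g2 = random_aln(3, 36, gene = "g2"))
  cats <- data.frame(gene_id = c("g1", "g2"),
                     category = c("freqA", "rareX"),
                     chromosome = c("A1", "X"), position = c(0.1, 0.5))
  raw <- stats_table(alns, cats)
  adj <- stats_table(alns, cats, adjust_pi = TRUE)
  is_auto <- adj$category == "freqA"
  expect_equal(adj$pi_1[is_auto], 0.75 * raw$pi_1[is_auto])
  expect_equal(adj$pi_1[!is_auto], raw$pi_1[!is_auto])
  expect_true(all(adj$pi_adjusted[is_auto]))
  expect_false(any(adj$pi_adjusted[!is_auto]))
})
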