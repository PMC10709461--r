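spmap4 <- data.frame(sample_id = paste0("S", 1:4),
                     species = rep(c("species1", "species2"), each = 2))

test_that("FASTA round trip is the identity on haplotype matrices", {
  set.seed(11)
  alns <- list(g1 = random_aln(2, 24, gene = "g1"),
               g2 = random_aln(2, 24, gene = "g2"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_gene_alignments(alns, f)
  back <- read_gene_alignments(f, spmap4)
  expect_length(back, 2L)
  expect_equal(nrow(back$g1$seqs), 8L)
  for (g in names(alns)) {
    expect_identical(unname(back[[g]]$seqs), unname(alns[[g]]$seqs))
    expect_identical(back[[g]]$species, alns[[g]]$species)
  }
})

test_that("lowercase and unknown characters are normalised on read", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|S1|1", "acgtX-", ">g1|S1|2", "ACGTNN",
               ">g1|S2|1", "aaaaaa", ">g1|S2|2", "cccccc",
               ">g1|S3|1", "gggggg", ">g1|S3|2", "tttttt",
               ">g1|S4|1", "acacac", ">g1|S4|2", "gtgtgt"), f)
  a <- read_gene_alignments(f, spmap4)$g1
  expect_identical(unname(a$seqs[1, ]), c("A", "C", "G", "T", "N", "-"))
  expect_identical(unname(a$seqs[2, ]), c("A", "C", "G", "T", "N", "N"))
})

test_that("malformed alignment inputs fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">gX|S1|1", "ACGT", ">gX|S1|2", "ACG",
               ">gX|S2|1", "ACGT", ">gX|S2|2", "ACGT",
               ">gX|S3|1", "ACGT", ">gX|S3|2", "ACGT",
               ">gX|S4|1", "ACGT", ">gX|S4|2", "ACGT"), f)
  expect_error(read_gene_alignments(f, spmap4), "gX")
  f2 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1|S9|1", "ACGT", ">g1|S9|2", "ACGT"), f2)
  expect_error(read_gene_alignments(f2, spmap4), "S9")
  expect_error(hap_alignment("g", matrix("A", 3, 2), "S1", "sp1"),
               "2 rows per sample")
})

test_that("expression matrix TSV round trip preserves values and contracts hold", {
  m <- matrix(c(0, 1.5, 2, 3, 4.25, 5, 6, 7, 8, 9, 10, 11), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("S", 1:4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  back <- read_expression(f, spmap4)
  expect_equal(back$fpkm, m)
  expect_equal(rowSums(back$fpkm), rowSums(m))
  m2 <- m; m2[2, 3] <- -1
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m2, f2)
  expect_error(read_expression(f2), "g2.*S3|negative")
  expect_error(expression_matrix(m, spmap4[1:2, ]), "missing")
})

test_that("gene category tables validate labels and uniqueness", {
  d <- data.frame(gene_id = c("a", "b"), category = c("freqA", "rareX"),
                  chromosome = "A1", position = c(0.1, 0.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_categories(d, f)
  back <- read_gene_categories(f)
  expect_s3_class(back$category, "factor")
  expect_identical(levels(back$category), c("freqA", "rareA", "freqX", "rareX"))
  expect_error(validate_gene_categories(
    data.frame(gene_id = "a", category = "weird")), "weird")
  expect_error(validate_gene_categories(
    data.frame(gene_id = c("a", "a"), category = "freqA")), "duplicated")
})

# --- VCF conversion ------------------------------------------------------

write_toy_vcf <- function(path, rows,
                          samples = c("S1", "S2", "S3", "S4")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=geneA,length=12>"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
}

ref_cds <- c(geneA = "ACGTACGTACGT")

test_that("VCF pseudo-haplotypes honour genotype and phasing rules", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "geneA\t2\t.\tC\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "geneA\t5\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0\t0/0"))
  out <- vcf_to_pseudohaplotypes(f, ref_cds, spmap4,
                                 phasing = "ref_alt_split")
  a <- out$geneA
  expect_equal(dim(a$seqs), c(8L, 12L))
  # S1 homozygous ref at pos 2: both rows C
  expect_identical(unname(a$seqs[1:2, 2]), c("C", "C"))
  # S2 het 0/1 with ref_alt_split: row1 REF, row2 ALT
  expect_identical(unname(a$seqs[3:4, 2]), c("C", "A"))
  # S3 homozygous alt
  expect_identical(unname(a$seqs[5:6, 2]), c("A", "A"))
  # S4 missing genotype -> N on both rows
  expect_identical(unname(a$seqs[7:8, 2]), c("N", "N"))
  # non-variant positions copy the reference
  expect_identical(unname(a$seqs[1, 1]), "A")
})

test_that("random phasing is deterministic under a seed", {
  f <- withr::local_tempfile(fileext = ".vcf")
  rows <- vapply(c(1, 3, 5, 7, 9), function(p)
    sprintf("geneA\t%d\t.\t%s\tG\t.\tPASS\t.\tGT\t0/1\t0/1\t0/1\t0/1",
            p, substr(ref_cds, p, p)), "")
  write_toy_vcf(f, rows)
  a1 <- vcf_to_pseudohaplotypes(f, ref_cds, spmap4, "random", seed = 1)
  a2 <- vcf_to_pseudohaplotypes(f, ref_cds, spmap4, "random", seed = 1)
  a3 <- vcf_to_pseudohaplotypes(f, ref_cds, spmap4, "random", seed = 2)
  expect_identical(a1$geneA$seqs, a2$geneA$seqs)
  expect_false(identical(a1$geneA$seqs, a3$geneA$seqs))
})

test_that("indels are skipped and >2-allele sites masked, with logging", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(f, c(
    "geneA\t3\t.\tG\tGTT\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0\t0/0",
    "geneA\t6\t.\tC\tA,T\t.\tPASS\t.\tGT\t0/1\t1/2\t0/0\t0/2"))
  out <- vcf_to_pseudohaplotypes(f, ref_cds, spmap4, "ref_alt_split")
  a <- out$geneA
  expect_identical(unname(a$seqs[, 3]), rep("G", 8))  # indel: reference kept
  expect_identical(unname(a$seqs[, 6]), rep("N", 8))  # triallelic: masked
  log <- attr(out, "log")
  expect_equal(unname(log["indel_skipped"]), 1L)
  expect_equal(unname(log["multiallelic_masked"]), 1L)
})
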