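# Synthetic-data generator.
#
# Emulates the statistical structure of the study design: two diverged
# plant species (12 diploids each), four gene categories crossing
# chromosome type (autosome / X) with local recombination (frequent /
# rare), per-category isolation-with-migration demographies with
# two-class heterogeneous migration, codon-structured coding sequences
# whose first two codon positions are selectively constrained, and FPKM
# expression matrices in which a configured fraction of genes has
# species-shifted means. Every gene is simulated independently (free
# recombination between genes, none within).

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions. Each category gets an
#' IM2_2M demography (the best-supported model family: exponential growth
#' since the split and direction-specific, two-class migration, with the
#' low-migration class A more prevalent in rarely recombining categories)
#' and a per-site mutation scale theta for third codon positions; X-linked
#' categories use three quarters of the corresponding autosomal theta.
#' Expression divergence fractions mirror the 7-10% range of the study
#' design.
#'
#' @param genes_per_category named integer vector (freqA, rareA, freqX,
#'   rareX).
#' @param diploids_per_species diploid samples per species.
#' @param n_codons gene length in codons.
#' @param demography named list of [model_params] per category.
#' @param theta named numeric: per-site theta at third codon positions.
#' @param constraint relative mutation rate of codon positions 1-2.
#' @param expr_meanlog,expr_sdlog_gene log-normal distribution of per-gene
#'   mean FPKM across genes.
#' @param expr_sdlog_noise sample-to-sample log-scale noise within a gene.
#' @param expr_diverged_frac named numeric: fraction of genes per category
#'   with a species-shifted mean.
#' @param expr_shift size of the species shift on the natural-log FPKM
#'   scale (sign randomised per gene).
#' @param seed master seed; the whole dataset is deterministic given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(
    genes_per_category = c(freqA = 2009L, rareA = 1909L,
                           freqX = 209L, rareX = 398L),
    diploids_per_species = 12L,
    n_codons = 300L,
    demography = default_demographies(),
    theta = default_thetas(),
    constraint = 0.15,
    expr_meanlog = log(20), expr_sdlog_gene = 1,
    expr_sdlog_noise = 0.4,
    expr_diverged_frac = c(freqA = 0.072, rareA = 0.090,
                           freqX = 0.100, rareX = 0.100),
    expr_shift = 1.2,
    seed = 1L) {
  stopifnot(setequal(names(genes_per_category), CATEGORY_LEVELS),
            setequal(names(demography), CATEGORY_LEVELS),
            setequal(names(theta), CATEGORY_LEVELS),
            all(theta > 0), all(expr_diverged_frac >= 0),
            all(expr_diverged_frac <= 1), constraint >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Default per-category demographies
#'
#' IM2_2M parameter sets chosen to represent the emulated study
#' conditions: long-diverged populations with post-split growth,
#' direction-asymmetric migration, a low-migration site class A that is
#' more prevalent (P about 0.55) in rarely recombining categories than in
#' frequently recombining ones (P about 0.30), and an order-of-magnitude
#' contrast between class-A and class-B rates.
#'
#' @return named list of [model_params].
#' @export
default_demographies <- function() list(
  freqA = model_params("IM2_2M", s = 0.38, N1 = 1.38, N2 = 2.36, T = 0.55,
                       MA1 = 0.38, MA2 = 0.39, MB1 = 7.90, MB2 = 0.52,
                       P = 0.30),
  rareA = model_params("IM2_2M", s = 0.27, N1 = 1.82, N2 = 2.48, T = 4.84,
                       MA1 = 0.10, MA2 = 0.11, MB1 = 2.52, MB2 = 0.75,
                       P = 0.55),
  freqX = model_params("IM2_2M", s = 0.65, N1 = 1.62, N2 = 1.95, T = 3.77,
                       MA1 = 0.15, MA2 = 0.18, MB1 = 2.50, MB2 = 1.26,
                       P = 0.30),
  rareX = model_params("IM2_2M", s = 0.29, N1 = 1.20, N2 = 1.24, T = 3.85,
                       MA1 = 0.04, MA2 = 0.13, MB1 = 3.13, MB2 = 2.88,
                       P = 0.55))

#' Default per-category mutation scales
#'
#' Third-codon-position theta per site, calibrated once against the
#' emulated diversity levels (fourfold-degenerate pi of roughly 0.033 for
#' freqA and 0.011 for rareA, with X-linked categories at 75% of the
#' corresponding autosomal value to reflect their three-quarter effective
#' size) given the expected within-species pairwise coalescence time of
#' each category's default demography.
#'
#' @return named numeric vector.
#' @export
default_thetas <- function() c(freqA = 0.0298, rareA = 0.0054,
                               freqX = 0.0137, rareX = 0.0057)

SENSE_CODONS <- local({
  b <- c("T", "C", "A", "G")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

#' Drop mutations on a genealogy to produce a gene alignment
#'
#' Infinite-sites-style mutation: the number of mutations at each site is
#' Poisson with mean `branch length total * theta/2 * c`, where the
#' constraint factor `c` is 1 at third codon positions and `constraint` at
#' the first two (emulating purifying selection on amino-acid-changing
#' positions); each mutation picks a branch proportionally to its length
#' and substitutes a random different base in all descendant leaves. The
#' ancestral sequence is drawn codon-wise from the 61 sense codons.
#'
#' @param g a `genealogy` from [simulate_genealogy()].
#' @param theta_per_site third-position theta per site.
#' @param n_codons gene length in codons.
#' @param gene_id identifier for the resulting alignment.
#' @param codon_structure apply the position-1/2 constraint factor.
#' @param constraint relative rate at codon positions 1-2.
#' @param sample_ids,species optional sample metadata; defaults pair
#'   consecutive haplotypes into diploids named by species.
#' @return [hap_alignment] with attributes `ancestral` (ancestral
#'   sequence) and `n_mutations`.
#' @export
drop_mutations <- function(g, theta_per_site, n_codons, gene_id = "gene",
                           codon_structure = TRUE, constraint = 0.15,
                           sample_ids = NULL, species = NULL) {
  stopifnot(theta_per_site >= 0, n_codons >= 1)
  n <- g$n1 + g$n2
  n_sites <- 3L * n_codons
  anc <- unlist(strsplit(sample(SENSE_CODONS, n_codons, replace = TRUE), ""))
  mat <- matrix(rep(anc, each = n), nrow = n)
  L_tot <- total_branch_length(g)
  pos_in_codon <- rep(1:3, n_codons)
  rate <- theta_per_site / 2 *
    (if (codon_structure) ifelse(pos_in_codon == 3L, 1, constraint) else 1)
  n_mut <- rpois(n_sites, rate * L_tot)
  hit <- which(n_mut > 0L)
  if (length(hit)) {
    # pre-decode branch descendant sets; apply ancestral-most (largest
    # descendant set) mutations first so nested masks see a consistent base
    desc <- lapply(g$branch_mask, decode_mask, n = n)
    sizes <- lengths(desc)
    for (s0 in hit) {
      br <- sample.int(length(g$branch_length), n_mut[s0], replace = TRUE,
                       prob = g$branch_length)
      for (b in br[order(-sizes[br])]) {
        rows <- desc[[b]]
        cur <- mat[rows[1L], s0]
        mat[rows, s0] <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
  }
  sample_ids <- sample_ids %||%
    paste0(rep(c("sp1_S", "sp2_S"), c(g$n1 / 2, g$n2 / 2)),
           sprintf("%02d", c(seq_len(g$n1 / 2), seq_len(g$n2 / 2))))
  species <- species %||% rep(c("species1", "species2"),
                              c(g$n1 / 2, g$n2 / 2))
  out <- hap_alignment(gene_id, mat, sample_ids, species, frame_offset = 0L)
  attr(out, "ancestral") <- paste(anc, collapse = "")
  attr(out, "n_mutations") <- sum(n_mut)
  out
}

#' Simulate a complete synthetic dataset
#'
#' Generates, per gene category, independent genealogies under the
#' category's demography, codon-structured alignments, a gene-category
#' table with genome positions (rare categories occupy the central band of
#' their chromosome), and FPKM matrices for both species with the
#' configured fraction of expression-diverged genes. Fully deterministic
#' under the master seed.
#'
#' @param config a [sim_config].
#' @return list with `alignments` (named list of [hap_alignment]),
#'   `categories` (gene category table), `expression`
#'   ([expression_matrix]), `ancestral` (named vector) and `truth`
#'   (per-category parameters plus per-gene migration class and
#'   expression-shift record).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nd <- config$diploids_per_species
  n1 <- 2L * nd
  sample_ids <- paste0(rep(c("sp1_S", "sp2_S"), each = nd),
                       sprintf("%02d", rep(seq_len(nd), 2L)))
  species <- rep(c("species1", "species2"), each = nd)
  alns <- list()
  cat_rows <- list()
  truth_genes <- list()
  for (cat in CATEGORY_LEVELS) {
    G <- config$genes_per_category[[cat]]
    if (G == 0L) next
    pars <- config$demography[[cat]]
    th <- config$theta[[cat]]
    seeds <- sample.int(.Machine$integer.max, G)
    chrom <- if (grepl("X", cat)) "X" else "A1"
    central <- grepl("rare", cat)
    pos <- if (central) runif(G, 0.25, 0.75) else
      ifelse(runif(G) < 0.5, runif(G, 0, 0.25), runif(G, 0.75, 1))
    for (i in seq_len(G)) {
      gid <- sprintf("%s_%04d", cat, i)
      gen <- simulate_genealogy(pars, n1, n1, seed = seeds[i])
      alns[[gid]] <- drop_mutations(
        gen, th, config$n_codons, gene_id = gid,
        constraint = config$constraint,
        sample_ids = sample_ids, species = species)
      truth_genes[[gid]] <- data.frame(
        gene_id = gid, category = cat,
        migration_class = attr(gen, "migration_class"),
        stringsAsFactors = FALSE)
    }
    cat_rows[[cat]] <- data.frame(
      gene_id = sprintf("%s_%04d", cat, seq_len(G)), category = cat,
      chromosome = chrom, position = round(pos, 4),
      stringsAsFactors = FALSE)
  }
  categories <- validate_gene_categories(do.call(rbind, cat_rows))
  rownames(categories) <- NULL

  # expression: log-normal gene means; diverged genes shift one species
  G_all <- nrow(categories)
  mu <- rlnorm(G_all, config$expr_meanlog, config$expr_sdlog_gene)
  frac <- config$expr_diverged_frac[as.character(categories$category)]
  diverged <- rbinom(G_all, 1L, frac) == 1L
  shift <- ifelse(diverged, sample(c(-1, 1), G_all, replace = TRUE) *
                    config$expr_shift, 0)
  fpkm <- t(vapply(seq_len(G_all), function(i) {
    m1 <- rlnorm(nd, log(mu[i]), config$expr_sdlog_noise)
    m2 <- rlnorm(nd, log(mu[i]) + shift[i], config$expr_sdlog_noise)
    c(m1, m2)
  }, numeric(2L * nd)))
  dimnames(fpkm) <- list(categories$gene_id, sample_ids)
  expr <- expression_matrix(fpkm, data.frame(sample_id = sample_ids,
                                             species = species))
  truth <- list(
    config = config,
    demography = config$demography, theta = config$theta,
    genes = do.call(rbind, truth_genes),
    expression = data.frame(gene_id = categories$gene_id,
                            diverged = diverged, shift = shift,
                            mean_fpkm = mu, stringsAsFactors = FALSE))
  rownames(truth$genes) <- NULL
  list(alignments = alns, categories = categories, expression = expr,
       ancestral = vapply(alns, attr, "", "ancestral"), truth = truth)
}

#' Simulate an observed joint SFS directly from a model
#'
#' Draws independent Poisson counts around `theta * E` where `E` is the
#' Monte-Carlo expected branch-length spectrum — the exact generative
#' process assumed by the Poisson composite likelihood. Useful for
#' parameter-recovery experiments.
#'
#' @param params a [model_params].
#' @param n1,n2 haploid sample sizes.
#' @param theta mutation scale; alternatively give `target_mass` to set
#'   theta so the expected total number of sites equals it.
#' @param n_reps Monte-Carlo replicates for the expectation.
#' @param seed seed for both the expectation and the Poisson draw (kept
#'   distinct internally).
#' @param fold fold the spectrum.
#' @param target_mass optional expected total site count.
#' @return `joint_sfs` of counts, with attribute `theta`.
#' @export
simulate_observed_sfs <- function(params, n1, n2, theta = NULL,
                                  n_reps = 20000L, seed = 1L, fold = FALSE,
                                  target_mass = NULL) {
  E <- expected_sfs(params, n1, n2, n_reps = n_reps, seed = seed + 1000L,
                    fold = fold)
  if (is.null(theta)) {
    stopifnot(!is.null(target_mass))
    theta <- target_mass / sfs_mass(E)
  }
  set.seed(seed)
  counts <- matrix(rpois(length(E$counts), theta * E$counts),
                   nrow = n1 + 1L)
  out <- joint_sfs(counts, n1, n2, folded = fold)
  attr(out, "theta") <- theta
  out
}
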