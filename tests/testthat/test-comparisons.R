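test_that("Kruskal-Wallis matches a hand-ranked oracle and is label-invariant", {
  g <- list(a = c(1.2, 3.4, 2.2), b = c(5.1, 4.4, 6.0), c = c(0.5, 2.9))
  kw <- kruskal_wallis(g)
  # hand computation: H = (12 / (N (N+1))) * sum n_i rbar_i^2 - 3 (N+1)
  x <- unlist(g); r <- rank(x); N <- length(x)
  grp <- rep(seq_along(g), lengths(g))
  H <- 12 / (N * (N + 1)) * sum(tapply(r, grp, function(z)
    length(z) * mean(z)^2)) - 3 * (N + 1)
  expect_equal(kw$H, H, tolerance = 1e-12)
  expect_equal(kw$df, 2L)
  # permuting group labels on identical data leaves H unchanged
  expect_equal(kruskal_wallis(g[c(3, 1, 2)])$H, kw$H)
  # fully degenerate data
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1)))$H, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1)))$p, 1)
})

test_that("compact letters separate shifted groups and match the p matrix", {
  # identical data: a single shared letter, guaranteed
  same <- list(a = rep(c(1, 2, 3), 5), b = rep(c(1, 2, 3), 5),
               c = rep(c(1, 2, 3), 5), d = rep(c(1, 2, 3), 5))
  r0 <- pairwise_wilcoxon_letters(same)
  expect_true(all(r0$letters == "a"))
  # four well-separated location-shifted groups: four distinct letters
  set.seed(6)
  base <- rnorm(100)
  shift <- 3 * IQR(base)
  gg <- list(g1 = base, g2 = base + shift, g3 = base + 2 * shift,
             g4 = base + 3 * shift)
  r1 <- pairwise_wilcoxon_letters(gg)
  expect_equal(length(unique(r1$letters)), 4L)
  expect_true(letters_consistent(r1$letters, r1$pairwise_p, r1$alpha))
  # mixed case: re-assert consistency on partially overlapping groups
  set.seed(8)
  gm <- list(a = rnorm(60), b = rnorm(60, 0.1), c = rnorm(60, 2),
             d = rnorm(60, 2.1))
  r2 <- pairwise_wilcoxon_letters(gm)
  expect_true(letters_consistent(r2$letters, r2$pairwise_p, r2$alpha))
  expect_error(pairwise_wilcoxon_letters(list(a = 1:3, b = numeric(0))),
               "empty")
})

test_that("with two groups, Kruskal-Wallis orders like the Wilcoxon statistic", {
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20, runif(1, 0, 2))
    # without continuity correction, H = z^2 of the rank-sum statistic,
    # so the two p-values coincide exactly
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                      correct = FALSE))$p.value
    kp <- kruskal_wallis(list(x, y))$p
    expect_equal(kp, w, tolerance = 1e-9)
  }
})

test_that("Spearman correlation equals rank-then-Pearson", {
  x <- c(2, 5, 1, 9, 7)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30) + 0.5 * a
  expect_equal(spearman_correlation(a, b)$rho, cor(rank(a), rank(b)),
               tolerance = 1e-12)
  expect_true(is.na(spearman_correlation(rep(1, 5), 1:5)$rho))
})

test_that("2x2 chi-square equals the expected-counts formula", {
  expect_equal(chi_square_2x2(10, 90, 20, 180)$chi2, 0)
  # the gene-count comparison of the two autosomal categories
  cs <- chi_square_2x2(145, 1864, 172, 1737)
  hand <- local({
    m <- matrix(c(145, 1864, 172, 1737), 2, 2, byrow = TRUE)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  })
  expect_equal(cs$chi2, hand, tolerance = 1e-12)
  # swapping the rows changes nothing
  expect_equal(chi_square_2x2(172, 1737, 145, 1864)$chi2, cs$chi2)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("expression divergence tabulates counts, percentages and r2 correctly", {
  set.seed(44)
  nd <- 6
  samples <- paste0(rep(c("sp1_", "sp2_"), each = nd), 1:nd)
  spmap <- data.frame(sample_id = samples,
                      species = rep(c("species1", "species2"), each = nd))
  G <- 120
  cats <- data.frame(gene_id = sprintf("g%03d", 1:G),
                     category = rep(c("freqA", "rareA", "freqX", "rareX"),
                                    each = G / 4),
                     chromosome = "A1", position = runif(G))
  mu <- rlnorm(G, log(20), 1)
  shifted <- rep(FALSE, G); shifted[seq(1, G, by = 10)] <- TRUE
  fpkm <- t(vapply(1:G, function(i) {
    c(rlnorm(nd, log(mu[i]), 0.2),
      rlnorm(nd, log(mu[i]) + ifelse(shifted[i], 2.5, 0), 0.2))
  }, numeric(2 * nd)))
  dimnames(fpkm) <- list(cats$gene_id, samples)
  ed <- expression_divergence(expression_matrix(fpkm, spmap), cats)
  b <- ed$by_category
  # percentages recompute exactly from counts
  expect_equal(b$percent, 100 * b$significant / b$total)
  # margins sum: all = sum over the four categories
  expect_equal(b$total[b$cell == "all"], G)
  four <- b[b$cell %in% c("freqA", "rareA", "freqX", "rareX"), ]
  expect_equal(sum(four$significant), b$significant[b$cell == "all"])
  # identical matrices for both species: nothing significant
  fpkm2 <- cbind(fpkm[, 1:nd], fpkm[, 1:nd])
  colnames(fpkm2) <- samples
  ed2 <- expression_divergence(expression_matrix(fpkm2, spmap), cats)
  expect_equal(ed2$by_category$significant, rep(0L, 9),
               ignore_attr = TRUE)
  # r2 grid is 3x3 and within [0, 1]
  grid <- report_r2_grid(ed)
  expect_equal(dim(grid), c(3L, 4L))
  expect_true(all(grid[, -1] >= 0 & grid[, -1] <= 1))
})

test_that("zero-variance genes get the documented degenerate p-values", {
  nd <- 3
  samples <- paste0(rep(c("a", "b"), each = nd), 1:nd)
  spmap <- data.frame(sample_id = samples,
                      species = rep(c("species1", "species2"), each = nd))
  fpkm <- rbind(g1 = c(5, 5, 5, 5, 5, 5),      # constant, equal means
                g2 = c(5, 5, 5, 9, 9, 9))      # constant, different means
  colnames(fpkm) <- samples
  cats <- data.frame(gene_id = c("g1", "g2"), category = "freqA",
                     chromosome = "A1", position = c(0.1, 0.2))
  ed <- expression_divergence(expression_matrix(fpkm, spmap), cats)
  expect_equal(ed$per_gene$p, c(1, 0))
})
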