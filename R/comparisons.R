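# Category-wise nonparametric comparisons and expression divergence.

#' Kruskal-Wallis test over groups
#'
#' Rank-based H statistic with tie correction (via [stats::kruskal.test()])
#' and a chi-square p-value on `groups - 1` degrees of freedom. The fully
#' degenerate case (every value identical) returns `H = 0`, `p = 1`.
#'
#' @param groups named list of numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L))
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  k <- kruskal.test(groups)
  list(H = unname(k$statistic), p = k$p.value, df = unname(k$parameter))
}

#' Pairwise Wilcoxon rank-sum tests with compact letter display
#'
#' Mann-Whitney U with normal approximation and tie correction for every
#' pair of groups, then letters assigned by insert-and-absorb so that two
#' groups share a letter if and only if their pairwise test is not
#' significant at `alpha`.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the letter grouping.
#' @param p_adjust multiplicity correction applied to the pairwise
#'   p-values before lettering (`"none"` by default, `"holm"` available).
#' @param statistic label carried into the result.
#' @return object of class `group_comparison`: `kw` (Kruskal-Wallis),
#'   `pairwise_p` matrix, `letters`, `medians`, `n`.
#' @export
pairwise_wilcoxon_letters <- function(groups, alpha = 0.05,
                                      p_adjust = c("none", "holm"),
                                      statistic = "statistic") {
  p_adjust <- match.arg(p_adjust)
  stopifnot(length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("empty group")
  g <- length(groups)
  nm <- names(groups) %||% paste0("g", seq_len(g))
  P <- matrix(NA_real_, g, g, dimnames = list(nm, nm))
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    xi <- groups[[i]]; xj <- groups[[j]]
    p <- if (length(unique(c(xi, xj))) == 1L) 1 else
      suppressWarnings(wilcox.test(xi, xj, exact = FALSE)$p.value)
    P[i, j] <- P[j, i] <- p
  }
  if (p_adjust == "holm") {
    up <- upper.tri(P)
    P[up] <- stats::p.adjust(P[up], "holm")
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  letters <- cld_insert_absorb(P < alpha)
  structure(list(statistic = statistic, groups = nm,
                 kw = kruskal_wallis(groups), pairwise_p = P,
                 letters = setNames(letters, nm),
                 medians = vapply(groups, median, 0, na.rm = TRUE),
                 n = lengths(groups), alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$statistic, "- Kruskal-Wallis H =",
      format(x$kw$H, digits = 4), ", p =", format(x$kw$p, digits = 3), "\n")
  print(data.frame(group = x$groups, n = as.integer(x$n),
                   median = signif(x$medians, 4),
                   letters = x$letters, row.names = NULL))
  invisible(x)
}

# insert-and-absorb compact letter display from a logical matrix of
# significant differences (TRUE = the pair differs)
cld_insert_absorb <- function(sig) {
  g <- nrow(sig)
  cols <- list(rep(TRUE, g))                  # letter columns: group sets
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    if (!isTRUE(sig[i, j])) next
    for (ci in seq_along(cols)) {
      if (cols[[ci]][i] && cols[[ci]][j]) {
        a <- cols[[ci]]; b <- cols[[ci]]
        a[j] <- FALSE; b[i] <- FALSE
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb: drop columns whose set is a subset of another column's
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[cj]][cols[[ci]]]) &&
          !identical(cols[[ci]], cols[[cj]])) keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  lab <- letters[seq_along(cols)]
  vapply(seq_len(g), function(i)
    paste(lab[vapply(cols, `[`, TRUE, i)], collapse = ""), "")
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average) ranks, p-value via the t
#' approximation. Undefined (NA rho) when either variable has zero rank
#' variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default (configurable), df = 1.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @param correct apply the Yates continuity correction.
#' @return list with `chi2`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correct = FALSE) {
  m <- matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE)
  stopifnot(all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("chi-square undefined: zero margin")
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}

#' Interspecific gene-expression divergence
#'
#' Per-gene Welch two-sample t-test on FPKM between the two species,
#' significance at `alpha` (default 1e-4), tabulated per gene category and
#' for the margins {X, A, all} x {freq, rare, all} together with the
#' squared Pearson correlation of per-gene species-mean FPKM, and pairwise
#' chi-square comparisons of the significant proportions between the four
#' categories.
#'
#' @param expr an [expression_matrix] with a two-species sample map.
#' @param categories gene category table.
#' @param alpha per-gene significance threshold.
#' @param log_scale compute the r-squared on log10(FPKM + 1) means.
#' @param welch use the unequal-variance t-test (pooled if `FALSE`).
#' @return object of class `expression_divergence`: `per_gene` (gene,
#'   category, means, p, significant), `by_category` (counts, percent,
#'   r-squared per cell), `pairwise_chi2`.
#' @export
expression_divergence <- function(expr, categories, alpha = 1e-4,
                                  log_scale = FALSE, welch = TRUE) {
  stopifnot(inherits(expr, "expression_matrix"), !is.null(expr$species))
  sps <- unique(expr$species)
  i1 <- which(expr$species == sps[1]); i2 <- which(expr$species == sps[2])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need >= 2 samples per species")
  common <- intersect(rownames(expr$fpkm), categories$gene_id)
  m <- expr$fpkm[common, , drop = FALSE]
  cat_of <- setNames(as.character(categories$category), categories$gene_id)
  pvals <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, i1]; y <- m[i, i2]
    if (sd(x) == 0 && sd(y) == 0)
      return(if (mean(x) == mean(y)) 1 else 0)
    t.test(x, y, var.equal = !welch)$p.value
  }, 0)
  per_gene <- data.frame(
    gene_id = common, category = cat_of[common],
    mean_1 = rowMeans(m[, i1, drop = FALSE]),
    mean_2 = rowMeans(m[, i2, drop = FALSE]),
    p = pvals, significant = pvals < alpha,
    row.names = NULL, stringsAsFactors = FALSE)

  cells <- list(
    freqX = "freqX", freqA = "freqA", rareX = "rareX", rareA = "rareA",
    freq_all = c("freqA", "freqX"), rare_all = c("rareA", "rareX"),
    all_X = c("freqX", "rareX"), all_A = c("freqA", "rareA"),
    all = CATEGORY_LEVELS)
  by_cat <- do.call(rbind, lapply(names(cells), function(cl) {
    sub <- per_gene[per_gene$category %in% cells[[cl]], ]
    x <- sub$mean_1; y <- sub$mean_2
    if (log_scale) { x <- log10(x + 1); y <- log10(y + 1) }
    r2 <- if (nrow(sub) >= 3L && sd(x) > 0 && sd(y) > 0)
      cor(x, y)^2 else NA_real_
    data.frame(cell = cl, total = nrow(sub), significant = sum(sub$significant),
               percent = 100 * sum(sub$significant) / max(1L, nrow(sub)),
               r_squared = r2, stringsAsFactors = FALSE)
  }))
  pw <- {
    cats <- CATEGORY_LEVELS
    out <- NULL
    for (i in 1:3) for (j in (i + 1):4) {
      ti <- by_cat[by_cat$cell == cats[i], ]
      tj <- by_cat[by_cat$cell == cats[j], ]
      if (ti$total == 0 || tj$total == 0) next
      cs <- tryCatch(chi_square_2x2(ti$significant, ti$total - ti$significant,
                                    tj$significant, tj$total - tj$significant),
                     error = function(e) list(chi2 = NA_real_, p = NA_real_))
      out <- rbind(out, data.frame(cat1 = cats[i], cat2 = cats[j],
                                   chi2 = cs$chi2, p = cs$p,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  structure(list(per_gene = per_gene, by_category = by_cat,
                 pairwise_chi2 = pw, alpha = alpha, species = sps),
            class = "expression_divergence")
}

#' @export
print.expression_divergence <- function(x, ...) {
  cat("<expression_divergence> t-test at P <", format(x$alpha), "\n")
  print(x$by_category, row.names = FALSE)
  invisible(x)
}

#' Compare one statistic across the four gene categories
#'
#' Convenience wrapper: splits a [stats_table()] column by category for a
#' given site class, drops undefined values (listwise, with counts
#' recorded), and runs [pairwise_wilcoxon_letters()].
#'
#' @param stats output of [stats_table()].
#' @param column statistic column name (e.g. `"pi_1"`, `"fst"`).
#' @param site_class site class to use.
#' @param ... passed to [pairwise_wilcoxon_letters()].
#' @export
compare_categories <- function(stats, column, site_class = "fourfold", ...) {
  sub <- stats[stats$site_class == site_class & !is.na(stats$category), ]
  groups <- split(sub[[column]], factor(sub$category, CATEGORY_LEVELS))
  n_undef <- vapply(groups, function(v) sum(is.na(v)), 0L)
  groups <- lapply(groups, function(v) v[!is.na(v)])
  groups <- groups[lengths(groups) > 0L]   # categories with no defined value
  if (length(groups) < 2L)
    stop("fewer than two categories with defined ", column, " values")
  res <- pairwise_wilcoxon_letters(groups, statistic = column, ...)
  res$n_undefined <- n_undef
  res$site_class <- site_class
  res
}
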