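# R-facing wrappers around the structured-coalescent engine.

#' Simulate one structured-coalescent genealogy
#'
#' Backward-in-time simulation for `n1 + n2` haploid lineages sampled from
#' the two present-day populations of a demographic model: coalescence at
#' rate `choose(k,2)/nu_deme(t)` within each deme, backward migration at
#' rate `M/2` per lineage, exponential deme-size trajectories from
#' `(s, 1-s)` at the split to `(N1, N2)` now, and a panmictic ancestral
#' deme of size 1 beyond the split. For heterogeneous-migration models a
#' migration class (A with probability `P`) is drawn first.
#'
#' @param params a [model_params] object.
#' @param n1,n2 haploid sample sizes per species.
#' @param seed integer engine seed (same seed, same genealogy).
#' @return object of class `genealogy`: per-branch lengths, descendant
#'   bitmasks and species-wise descendant counts, merge records
#'   (`parent`, `node_time`; leaves `1..n1` are species 1, `n1+1..n1+n2`
#'   species 2, internal nodes numbered in coalescence order) and `tmrca`.
#'   Attribute `migration_class` records the drawn class for mixture
#'   models.
#' @export
simulate_genealogy <- function(params, n1, n2, seed = 1L) {
  stopifnot(inherits(params, "model_params"))
  calls <- .engine_calls(params)
  cls <- 1L
  if (length(calls) == 2L) {            # mixture: draw the migration class
    set.seed(seed)
    cls <- if (runif(1) < calls[[1]]$w) 1L else 2L
  }
  a <- calls[[cls]][[1]]
  g <- cpp_simulate_genealogy(a$N1, a$N2, a$s, a$T, a$m1, a$m2, a$growth,
                              as.integer(n1), as.integer(n2),
                              as.double(seed))
  g$n1 <- as.integer(n1)
  g$n2 <- as.integer(n2)
  g$leaf_species <- rep(c("species1", "species2"), c(n1, n2))
  attr(g, "migration_class") <- c("A", "B")[cls]
  class(g) <- "genealogy"
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", x$n1, "+", x$n2, "leaves, TMRCA =",
      format(x$tmrca, digits = 4), "\n")
  invisible(x)
}

#' Total branch length of a genealogy
#' @param g a `genealogy`.
#' @export
total_branch_length <- function(g) sum(g$branch_length)

#' Convert a genealogy to an ape phylogeny
#'
#' @param g a `genealogy`.
#' @return an `ape::phylo` object (ultrametric, leaf labels
#'   `sp1_1..`/`sp2_1..`).
#' @export
genealogy_to_phylo <- function(g) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the ape package is required for phylo export")
  n <- g$n1 + g$n2
  parent <- g$parent                    # 1-based, root = 0
  root <- which(parent == 0L)
  # ape numbering: tips 1..n, root n+1, internals n+2..
  nodes <- seq_along(parent)
  internal <- setdiff(nodes, seq_len(n))
  remap <- integer(length(nodes))
  remap[seq_len(n)] <- seq_len(n)
  remap[root] <- n + 1L
  remap[setdiff(internal, root)] <-
    n + 1L + seq_along(setdiff(internal, root))
  child <- setdiff(nodes, root)
  edge <- cbind(remap[parent[child]], remap[child])
  edge_len <- g$node_time[parent[child]] - g$node_time[child]
  tip.label <- c(paste0("sp1_", seq_len(g$n1)),
                 paste0("sp2_", seq_len(g$n2)))
  tr <- list(edge = edge, edge.length = edge_len, Nnode = n - 1L,
             tip.label = tip.label)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# decode a descendant bitmask (exact double encoding) into leaf indices
decode_mask <- function(mask, n) {
  which(floor(mask / 2^(0:(n - 1))) %% 2 == 1)
}
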