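# End-to-end orchestration: simulate -> stats -> comparisons -> SFS ->
# demographic fits -> expression divergence, with a reproducibility
# manifest. Stages write plain-text outputs under `out_dir` and are
# skipped on re-run when their output exists and the configuration hash
# is unchanged.

#' Run the full synthetic analysis pipeline
#'
#' @param config a [sim_config] describing the dataset.
#' @param out_dir output directory (created if missing).
#' @param seed master seed for the analysis stages (simulation uses
#'   `config$seed`).
#' @param sfs_n1,sfs_n2 projection sizes for the joint spectra.
#' @param fit_models model names fitted per gene category.
#' @param fit_reps,fit_stage_runs,fit_maxit optimisation settings
#'   (protocol default is stage runs 10 and 30; reduce for quick runs).
#' @param n_boot bootstrap replicates for the best model's CIs (0 skips).
#' @param overwrite re-run stages even when outputs exist and the config
#'   is unchanged.
#' @return invisible manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1L,
                         sfs_n1 = 20L, sfs_n2 = 20L,
                         fit_models = c("IM2", "IM2_2M"),
                         fit_reps = 2000L, fit_stage_runs = c(10L, 30L),
                         fit_maxit = 150L, n_boot = 0L,
                         overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  cfg_hash <- config_hash(list(config = unclass(config), seed = seed,
                               sfs = c(sfs_n1, sfs_n2),
                               models = fit_models, reps = fit_reps,
                               runs = fit_stage_runs, maxit = fit_maxit,
                               boot = n_boot))
  manifest <- list(package_version = as.character(utils::packageVersion("periflow")),
                   config_hash = cfg_hash, seed = seed,
                   sim_seed = config$seed, stages = list(), warnings = list())
  hash_file <- file.path(out_dir, "config.hash")
  fresh <- overwrite || !file.exists(hash_file) ||
    readLines(hash_file)[1] != cfg_hash
  writeLines(cfg_hash, hash_file)
  stage <- function(name, outputs, fun) {
    paths <- file.path(out_dir, outputs)
    t0 <- Sys.time()
    skipped <- !fresh && all(file.exists(paths))
    val <- if (skipped) NULL else fun(paths)
    manifest$stages[[name]] <<- list(
      skipped = skipped,
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2),
      outputs = as.list(setNames(unname(tools::md5sum(paths)), outputs)))
    val
  }

  sim <- stage("simulate",
               c("alignments.fasta", "categories.tsv", "expression.tsv"),
               function(paths) {
    d <- simulate_dataset(config)
    write_gene_alignments(d$alignments, paths[1])
    write_gene_categories(d$categories, paths[2])
    write_expression(d$expression, paths[3])
    d
  })
  if (is.null(sim)) {       # stage skipped: reload inputs from disk
    spmap <- data.frame(
      sample_id = paste0(rep(c("sp1_S", "sp2_S"),
                             each = config$diploids_per_species),
                         sprintf("%02d", rep(seq_len(config$diploids_per_species), 2L))),
      species = rep(c("species1", "species2"),
                    each = config$diploids_per_species))
    sim <- list(
      alignments = read_gene_alignments(file.path(out_dir, "alignments.fasta"),
                                        spmap),
      categories = read_gene_categories(file.path(out_dir, "categories.tsv")),
      expression = read_expression(file.path(out_dir, "expression.tsv"),
                                   spmap))
  }

  stats <- stage("stats", "stats.tsv", function(paths) {
    s <- stats_table(sim$alignments, sim$categories)
    write.table(s, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    s
  }) %||% read.delim(file.path(out_dir, "stats.tsv"))

  stage("comparisons", "comparisons.tsv", function(paths) {
    specs <- list(c("pi_1", "fourfold"), c("pi_2", "fourfold"),
                  c("tajd_1", "fourfold"), c("tajd_2", "fourfold"),
                  c("fst", "all"), c("dxy", "all"),
                  c("zns_1", "all"), c("zns_2", "all"))
    rows <- do.call(rbind, lapply(specs, function(sp) {
      r <- tryCatch(compare_categories(stats, sp[1], sp[2]),
                    error = function(e) NULL)   # e.g. all values undefined
      if (is.null(r)) return(NULL)
      data.frame(statistic = sp[1], site_class = sp[2],
                 group = r$groups, n = as.integer(r$n),
                 median = r$medians, letters = r$letters,
                 kw_H = r$kw$H, kw_p = r$kw$p,
                 stringsAsFactors = FALSE)
    }))
    write.table(rows, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    rows
  })

  spectra <- stage("sfs", paste0("sfs_", CATEGORY_LEVELS, ".txt"),
                   function(paths) {
    out <- list()
    for (i in seq_along(CATEGORY_LEVELS)) {
      cat <- CATEGORY_LEVELS[i]
      ids <- sim$categories$gene_id[sim$categories$category == cat]
      if (!length(ids)) next
      s <- build_joint_sfs(sim$alignments[ids], sfs_n1, sfs_n2, fold = TRUE)
      write_sfs(s, paths[i])
      out[[cat]] <- s
    }
    out
  }) %||% setNames(lapply(file.path(out_dir, paste0("sfs_", CATEGORY_LEVELS, ".txt")),
                          read_sfs), CATEGORY_LEVELS)

  stage("fit", c("fits.tsv", "fits.json"), function(paths) {
    all_rows <- list()
    fits_json <- list()
    for (cat in names(spectra)) {
      fits <- lapply(fit_models, function(m)
        optimize_model(m, spectra[[cat]], seed = seed, n_reps = fit_reps,
                       stage_runs = fit_stage_runs, maxit = fit_maxit))
      tab <- report_model_table(fits)
      tab <- cbind(category = cat, tab)
      all_rows[[cat]] <- tab
      fits_json[[cat]] <- lapply(fits, function(f)
        list(model = f$model_id, loglik = f$loglik, theta = f$theta,
             aic = f$aic, params = as.list(as.numeric(f$params)) |>
               setNames(names(f$params))))
      if (n_boot > 0L) {
        best <- fits[[which.min(vapply(fits, `[[`, 0, "aic"))]]
        ids <- sim$categories$gene_id[sim$categories$category == cat]
        boots <- bootstrap_resample_sfs(sim$alignments[ids], n_boot,
                                        seed = seed, n1 = sfs_n1,
                                        n2 = sfs_n2, fold = TRUE)
        ci <- bootstrap_ci(best, boots, seed = seed)
        fits_json[[cat]]$ci <- ci
        write.table(ci, file.path(out_dir, paste0("ci_", cat, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    tab <- do.call(rbind, all_rows)
    write.table(tab, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(fits_json, paths[2], auto_unbox = TRUE,
                         digits = NA)
    tab
  })

  stage("expression", c("expression_divergence.tsv", "expression_r2.tsv"),
        function(paths) {
    ed <- expression_divergence(sim$expression, sim$categories)
    write.table(ed$by_category, paths[1], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(report_r2_grid(ed), paths[2], sep = "\t", quote = FALSE,
                row.names = FALSE)
    ed
  })

  manifest$total_seconds <- round(as.numeric(Sys.time() - t_start,
                                             units = "secs"), 2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Model-comparison report table
#'
#' One row per fitted model with the columns of a standard
#' model-selection report: free parameters, log-likelihood, theta, AIC,
#' delta AIC, relative likelihood, and for each nested pair found among
#' the fits the likelihood-ratio statistic and p-value against the
#' smaller model.
#'
#' @param fits list of `fit_result` objects on the same spectrum.
#' @return data frame.
#' @export
report_model_table <- function(fits) {
  tab <- model_selection_table(fits)
  nested <- list(IM_2M = "IM", IM2_2M = "IM2", IM = "split_mig",
                 IM2 = "IM")
  tab$lrt_2dll <- NA_real_
  tab$lrt_p <- NA_real_
  for (i in seq_len(nrow(tab))) {
    null_id <- nested[[tab$model[i]]]
    if (is.null(null_id)) next
    j <- match(null_id, tab$model)
    if (!is.na(j)) {
      l <- lrt(tab$loglik[j], tab$loglik[i], tab$k[i] - tab$k[j])
      tab$lrt_2dll[i] <- l$statistic
      tab$lrt_p[i] <- l$p
    }
  }
  par_strings <- vapply(fits, function(f)
    paste(sprintf("%s=%.3g", names(f$params), as.numeric(f$params)),
          collapse = ","), "")
  tab$params <- par_strings
  tab
}

#' Expression r-squared grid
#'
#' Reshapes [expression_divergence()] cells into the 3 x 3
#' {freq, rare, all} x {X, A, all} grid of squared correlations.
#'
#' @param ed an `expression_divergence` object.
#' @export
report_r2_grid <- function(ed) {
  b <- ed$by_category
  val <- function(cell) b$r_squared[b$cell == cell]
  data.frame(row = c("freq", "rare", "all"),
             X = c(val("freqX"), val("rareX"), val("all_X")),
             A = c(val("freqA"), val("rareA"), val("all_A")),
             all = c(val("freq_all"), val("rare_all"), val("all")))
}
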