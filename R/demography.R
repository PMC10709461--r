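# Isolation-with-migration demographic inference over the joint SFS.
#
# Five two-population models: split_mig (constant sizes, one symmetric
# migration rate), IM (exponential size change since the split, symmetric
# migration), IM2 (direction-specific migration), and the heterogeneous-
# migration mixtures IM_2M / IM2_2M in which a proportion P of sites
# exchanges migrants at class-A rates and the rest at class-B rates.
# Units follow the diffusion convention: sizes in N_A, time in 2*N_A
# generations, migration in 2*N_A*m. The expected spectrum comes from a
# Monte-Carlo structured coalescent (common random numbers across
# likelihood evaluations) and the fit maximises a Poisson composite
# likelihood with the mutation scale theta profiled out analytically.

MODEL_PARAM_NAMES <- list(
  split_mig = c("N1", "N2", "T", "M"),
  IM        = c("s", "N1", "N2", "T", "M"),
  IM_2M     = c("s", "N1", "N2", "T", "MA", "MB", "P"),
  IM2       = c("s", "N1", "N2", "T", "M1", "M2"),
  IM2_2M    = c("s", "N1", "N2", "T", "MA1", "MA2", "MB1", "MB2", "P"))

#' Demographic model parameter vector
#'
#' @param model_id one of `split_mig`, `IM`, `IM_2M`, `IM2`, `IM2_2M`.
#' @param ... named parameter values; required names per model are `N1`,
#'   `N2` (current sizes, units of the ancestral size N_A), `T` (split
#'   time, units of 2 N_A generations), `s` (relative size of population 1
#'   at the split; population 2 starts at 1-s), migration rates (`M`;
#'   `M1`/`M2` into population 1/2; `MA*`/`MB*` for the two site classes)
#'   in units of 2 N_A m, and the class-A proportion `P`.
#' @return object of class `model_params` (named numeric vector with a
#'   `model_id` attribute).
#' @export
model_params <- function(model_id, ...) {
  model_id <- match.arg(model_id, names(MODEL_PARAM_NAMES))
  want <- MODEL_PARAM_NAMES[[model_id]]
  v <- unlist(list(...))
  if (!setequal(names(v), want))
    stop(model_id, " needs parameters {", paste(want, collapse = ", "),
         "}, got {", paste(names(v), collapse = ", "), "}")
  v <- v[want]
  sizes <- v[names(v) %in% c("N1", "N2")]
  if (any(sizes <= 0)) stop("population sizes must be positive")
  if (v["T"] < 0) stop("split time must be non-negative")
  if ("s" %in% want && (v["s"] <= 0 || v["s"] >= 1))
    stop("s must lie in (0, 1)")
  if ("P" %in% want && (v["P"] < 0 || v["P"] > 1))
    stop("P must lie in [0, 1]")
  structure(v, model_id = model_id, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", attr(x, "model_id"), "-",
      paste(sprintf("%s=%.4g", names(x), as.numeric(x)), collapse = ", "),
      "\n")
  invisible(x)
}

n_free_params <- function(params_or_model) {
  id <- if (inherits(params_or_model, "model_params"))
    attr(params_or_model, "model_id") else params_or_model
  length(MODEL_PARAM_NAMES[[id]])
}

# resolve a model into one or two plain (m1, m2, growth) engine calls
.engine_calls <- function(params) {
  id <- attr(params, "model_id")
  p <- as.list(as.numeric(params))
  names(p) <- names(params)
  base <- list(N1 = p$N1, N2 = p$N2, s = p$s %||% 0.5, T = p$T,
               growth = id != "split_mig")
  switch(id,
    split_mig = list(list(c(base, m1 = p$M, m2 = p$M), w = 1)),
    IM        = list(list(c(base, m1 = p$M, m2 = p$M), w = 1)),
    IM2       = list(list(c(base, m1 = p$M1, m2 = p$M2), w = 1)),
    IM_2M     = list(list(c(base, m1 = p$MA, m2 = p$MA), w = p$P),
                     list(c(base, m1 = p$MB, m2 = p$MB), w = 1 - p$P)),
    IM2_2M    = list(list(c(base, m1 = p$MA1, m2 = p$MA2), w = p$P),
                     list(c(base, m1 = p$MB1, m2 = p$MB2), w = 1 - p$P)))
}

#' Expected joint SFS under a demographic model
#'
#' Monte-Carlo expectation of the branch-length spectrum (unit mutation
#' scale): structured-coalescent genealogies are simulated backward in
#' time under the model and each branch adds its length to the cell given
#' by its numbers of present-day descendants in the two species. For the
#' heterogeneous-migration models the result is the P-weighted mixture of
#' the two migration classes computed with the same random numbers.
#'
#' @param params a [model_params] object.
#' @param n1,n2 haploid sample sizes of the spectrum.
#' @param n_reps Monte-Carlo replicates (>= 1000 for inference use).
#' @param seed engine seed; fixing it across evaluations makes the
#'   likelihood surface deterministic (common random numbers).
#' @param fold return the folded expectation.
#' @return a `joint_sfs` of expected branch lengths.
#' @export
expected_sfs <- function(params, n1, n2, n_reps = 2000L, seed = 1L,
                         fold = FALSE) {
  stopifnot(inherits(params, "model_params"))
  calls <- .engine_calls(params)
  acc <- matrix(0, n1 + 1L, n2 + 1L)
  for (cl in calls) {
    a <- cl[[1]]
    if (cl$w == 0) next
    acc <- acc + cl$w *
      cpp_expected_sfs(a$N1, a$N2, a$s, a$T, a$m1, a$m2, a$growth,
                       n1, n2, as.integer(n_reps), as.double(seed))
  }
  out <- joint_sfs(acc, n1, n2, folded = FALSE)
  if (fold) out <- fold_sfs(out)
  out
}

#' Poisson composite log-likelihood of an observed spectrum
#'
#' Treats each spectrum cell as an independent Poisson count with mean
#' `theta * E_ij`; the mutation scale `theta` has the analytic optimum
#' `sum(obs) / sum(expected)` and is profiled out. Cells where the
#' expectation is zero but the observation is positive use a floor of
#' 1e-12 (counted in attribute `n_floored`).
#'
#' @param obs,expected `joint_sfs` objects of matching shape and folding.
#' @return list with `loglik` and `theta`.
#' @export
poisson_loglik <- function(obs, expected) {
  if (obs$n1 != expected$n1 || obs$n2 != expected$n2 ||
      obs$folded != expected$folded)
    stop("observed and expected spectra do not match in shape or folding")
  S <- obs$counts
  E <- expected$counts
  tot_E <- sum(E)
  if (tot_E <= 0) stop("expected spectrum has no mass")
  theta <- sum(S) / tot_E
  if (theta == 0)
    return(list(loglik = 0, theta = 0))      # degenerate all-zero data
  mu <- theta * E
  n_floored <- sum(mu == 0 & S > 0)
  mu[mu == 0 & S > 0] <- 1e-12
  use <- mu > 0 | S > 0
  ll <- sum(S[use] * log(mu[use]) - mu[use] - lgamma(S[use] + 1))
  structure(list(loglik = ll, theta = theta), n_floored = n_floored)
}

#' Akaike information criterion
#' @param loglik maximised log-likelihood.
#' @param k number of free parameters.
#' @export
aic <- function(loglik, k) 2 * k - 2 * loglik

#' Likelihood-ratio test for nested models
#'
#' @param loglik_null,loglik_alt maximised log-likelihoods of the nested
#'   and the richer model.
#' @param df difference in number of free parameters.
#' @return list with `statistic` (2 * delta log-likelihood, floored at 0
#'   with a warning when the richer model fits worse) and `p` (chi-square
#'   upper tail).
#' @export
lrt <- function(loglik_null, loglik_alt, df) {
  stat <- 2 * (loglik_alt - loglik_null)
  if (stat < 0) {
    warning("alternative model fits worse than null; statistic set to 0")
    stat <- 0
  }
  list(statistic = stat, p = pchisq(stat, df, lower.tail = FALSE))
}

# ---- optimisation -------------------------------------------------------

# wide search ranges, as in the standard protocol: times 0-5, migration
# 0-10, sizes 0-100 (log-uniform starts need a positive floor)
default_ranges <- function(model_id) {
  nm <- MODEL_PARAM_NAMES[[model_id]]
  lo <- c(s = 0.05, N1 = 0.1, N2 = 0.1, T = 0.1, P = 0.05,
          M = 0.01, M1 = 0.01, M2 = 0.01, MA = 0.01, MB = 0.01,
          MA1 = 0.01, MA2 = 0.01, MB1 = 0.01, MB2 = 0.01)
  hi <- c(s = 0.98, N1 = 100, N2 = 100, T = 5, P = 0.98,
          M = 10, M1 = 10, M2 = 10, MA = 10, MB = 10,
          MA1 = 10, MA2 = 10, MB1 = 10, MB2 = 10)
  cbind(lo = lo[nm], hi = hi[nm])
}

.is_unit <- function(nm) nm %in% c("s", "P")   # logit-transformed params

.to_free <- function(v) {
  u <- .is_unit(names(v))
  out <- numeric(length(v))
  out[u] <- log(v[u] / (1 - v[u]))
  out[!u] <- log(v[!u])
  names(out) <- names(v)
  out
}

.from_free <- function(f) {
  u <- .is_unit(names(f))
  out <- numeric(length(f))
  out[u] <- 1 / (1 + exp(-f[u]))
  out[!u] <- exp(f[!u])
  names(out) <- names(f)
  out
}

.random_start <- function(ranges, rng_ignored = NULL) {
  nm <- rownames(ranges)
  v <- vapply(seq_along(nm), function(i) {
    if (.is_unit(nm[i])) runif(1, ranges[i, "lo"], ranges[i, "hi"])
    else exp(runif(1, log(ranges[i, "lo"]), log(ranges[i, "hi"])))
  }, 0)
  names(v) <- nm
  v
}

#' Fit a demographic model to an observed spectrum
#'
#' Two-stage multi-start Nelder-Mead on transformed parameters (log for
#' positive parameters, logit for `s` and `P`): `stage_runs[1]` starts are
#' drawn log-uniformly from the wide ranges (times 0-5, migration 0-10,
#' sizes 0-100), then ranges are tightened by a factor of 3 around the
#' stage-1 optimum (clipped to the wide ranges) for `stage_runs[2]`
#' further starts. The likelihood is evaluated with a fixed engine seed so
#' the surface each run sees is deterministic.
#'
#' @param model_id model name (see [model_params()]).
#' @param obs observed `joint_sfs`.
#' @param ranges optional 2-column matrix (`lo`, `hi`) of start ranges,
#'   rows named by parameter; defaults to the wide protocol ranges.
#' @param seed master seed for start draws and the engine.
#' @param n_reps Monte-Carlo replicates per likelihood evaluation.
#' @param stage_runs integer pair: runs in stages 1 and 2 (protocol
#'   default 10 and 30).
#' @param maxit Nelder-Mead iteration cap per run.
#' @param init optional list of extra start parameter vectors (named, on
#'   the natural scale), e.g. a nested model's optimum.
#' @param final_reps Monte-Carlo replicates for the final likelihood
#'   evaluation at the optimum (default `max(n_reps, 10000)`). A high-
#'   replicate final evaluation keeps reported log-likelihoods comparable
#'   across models: values maximised on a low-replicate surface partly
#'   reflect that surface's noise.
#' @return object of class `fit_result`: list with `params`
#'   ([model_params]), `loglik`, `theta`, `aic`, `k`, `runs` (per-run log)
#'   and `provenance` (seeds, ranges, settings).
#' @export
optimize_model <- function(model_id, obs, ranges = NULL, seed = 1L,
                           n_reps = 2000L, stage_runs = c(10L, 30L),
                           maxit = 150L, init = NULL, final_reps = NULL) {
  final_reps <- final_reps %||% max(n_reps, 10000L)
  model_id <- match.arg(model_id, names(MODEL_PARAM_NAMES))
  wide <- default_ranges(model_id)
  ranges <- ranges %||% wide
  eval_seed <- as.double(seed)
  negll <- function(free, reps) {
    v <- .from_free(free)
    p <- do.call(model_params, c(list(model_id), as.list(v)))
    e <- expected_sfs(p, obs$n1, obs$n2, n_reps = reps, seed = eval_seed,
                      fold = obs$folded)
    -poisson_loglik(obs, e)$loglik
  }
  run_one <- function(start, reps, iters) {
    f0 <- .to_free(start)
    if (iters == 0L)
      return(list(par = start, loglik = -negll(f0, reps),
                  convergence = NA_integer_))
    o <- optim(f0, negll, reps = reps, method = "Nelder-Mead",
               control = list(maxit = iters, reltol = 1e-7))
    list(par = .from_free(o$par), loglik = -o$value,
         convergence = o$convergence)
  }
  set.seed(seed)
  # cheap log-uniform screen of the wide ranges picks informed starts for
  # the stage-1 runs (the Monte-Carlo surface is too rough for blind
  # Nelder-Mead descents from arbitrary corners of a 4-9 dimensional box)
  reps0 <- max(200L, n_reps %/% 8L)
  kfree <- n_free_params(model_id)
  screen_pts <- lapply(seq_len(if (stage_runs[1] > 0L) 80L * kfree else 0L),
                       function(i) .random_start(ranges))
  screen_ll <- vapply(screen_pts, function(v) -negll(.to_free(v), reps0), 0)
  starts1 <- c(screen_pts[head(order(screen_ll, decreasing = TRUE),
                               stage_runs[1])],
               lapply(init, function(v) v[rownames(ranges)]))
  if (!length(starts1)) stop("no starts: stage_runs[1] = 0 and no init")
  # exploratory stage runs on a cheaper surface
  reps1 <- if (stage_runs[2] > 0L) max(300L, n_reps %/% 4L) else n_reps
  iters1 <- if (stage_runs[2] > 0L) max(100L, maxit %/% 2L) else maxit
  runs1 <- lapply(starts1, run_one, reps = reps1, iters = iters1)
  # stage 2: tighten around the best stage-1 optima (top 3, range factor 3)
  runs2 <- list()
  if (stage_runs[2] > 0L) {
    o1 <- order(vapply(runs1, `[[`, 0, "loglik"), decreasing = TRUE)
    tops <- runs1[head(o1, 3L)]
    alloc <- diff(round(seq(0, stage_runs[2], length.out = length(tops) + 1L)))
    starts2 <- list()
    for (ti in seq_along(tops)) {
      if (alloc[ti] == 0L) next
      b <- tops[[ti]]$par
      tight <- ranges
      for (i in seq_len(nrow(tight))) {
        nm <- rownames(tight)[i]
        if (.is_unit(nm)) {
          tight[i, ] <- c(max(wide[nm, "lo"], b[nm] - 0.15),
                          min(wide[nm, "hi"], b[nm] + 0.15))
        } else {
          tight[i, ] <- c(max(wide[nm, "lo"], b[nm] / 3),
                          min(wide[nm, "hi"], b[nm] * 3))
        }
      }
      starts2 <- c(starts2, list(b),
                   lapply(seq_len(max(0L, alloc[ti] - 1L)), function(i)
                     .random_start(tight)))
    }
    runs2 <- lapply(starts2, run_one, reps = n_reps, iters = maxit)
  }
  runs <- c(runs1, runs2)
  # polish: restart Nelder-Mead from the incumbent until it stops improving
  # (a fresh simplex escapes the shrunken one a capped run ends with)
  if (maxit > 0L) {
    for (pol in 1:3) {
      cur <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
      r <- run_one(cur$par, reps = n_reps, iters = maxit)
      runs[[length(runs) + 1L]] <- r
      if (r$loglik < cur$loglik + 1) break
    }
  }
  lls <- vapply(runs, `[[`, 0, "loglik")
  if (all(!is.finite(lls)))
    stop("all optimisation runs failed; check the observed spectrum")
  best <- runs[[which.max(lls)]]
  pbest <- do.call(model_params, c(list(model_id), as.list(best$par)))
  e <- expected_sfs(pbest, obs$n1, obs$n2, n_reps = final_reps,
                    seed = eval_seed, fold = obs$folded)
  pl <- poisson_loglik(obs, e)
  k <- n_free_params(model_id)
  structure(list(
    model_id = model_id, params = pbest, loglik = pl$loglik,
    theta = pl$theta, k = k, aic = aic(pl$loglik, k),
    runs = data.frame(
      run = seq_along(runs),
      stage = rep(1:3, c(length(runs1), length(runs2),
                         length(runs) - length(runs1) - length(runs2))),
      loglik = lls,
      convergence = vapply(runs, `[[`, 0L, "convergence")),
    provenance = list(seed = seed, eval_seed = eval_seed, n_reps = n_reps,
                      final_reps = final_reps,
                      stage_runs = stage_runs, maxit = maxit,
                      ranges = ranges)),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id, " loglik =", format(x$loglik),
      " theta =", format(x$theta), " AIC =", format(x$aic), "\n  ")
  print(x$params)
  invisible(x)
}

#' Model-selection table
#'
#' Ranks fits of competing models on the same observed spectrum by AIC and
#' reports the AIC difference to the best model and the relative
#' likelihood `exp(-delta_AIC / 2)`.
#'
#' @param fits list of `fit_result` objects.
#' @return data frame sorted as given, with `best` marking the minimum-AIC
#'   model.
#' @export
model_selection_table <- function(fits) {
  stopifnot(length(fits) >= 1L)
  aics <- vapply(fits, `[[`, 0, "aic")
  d <- data.frame(
    model = vapply(fits, `[[`, "", "model_id"),
    k = vapply(fits, `[[`, 0L, "k"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    theta = vapply(fits, `[[`, 0, "theta"),
    aic = aics,
    delta_aic = aics - min(aics),
    stringsAsFactors = FALSE)
  d$rel_like <- exp(-d$delta_aic / 2)
  d$best <- d$delta_aic == 0
  d
}

#' Bootstrap confidence intervals for a fitted model
#'
#' Refits the model to each bootstrap spectrum (single stage, `n_starts`
#' starts perturbed around the point estimate) and reports
#' `M +/- 1.96 * SD` per parameter, where M is the point estimate and SD
#' the standard deviation of the replicate estimates.
#'
#' @param fit a `fit_result`.
#' @param boot_spectra list of `joint_sfs` replicates (see
#'   [bootstrap_resample_sfs()]).
#' @param n_starts starts per replicate.
#' @param seed master seed.
#' @param n_reps,maxit engine replicates and iteration cap per refit.
#' @return data frame `param`, `estimate`, `sd`, `low`, `high`, with
#'   attribute `n_ok` (successful replicates).
#' @export
bootstrap_ci <- function(fit, boot_spectra, n_starts = 5L, seed = 1L,
                         n_reps = NULL, maxit = NULL) {
  n_reps <- n_reps %||% fit$provenance$n_reps
  maxit <- maxit %||% fit$provenance$maxit
  b0 <- as.numeric(fit$params)
  names(b0) <- names(fit$params)
  ests <- vector("list", length(boot_spectra))
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, length(boot_spectra))
  for (i in seq_along(boot_spectra)) {
    set.seed(rep_seeds[i])
    starts <- c(list(b0), lapply(seq_len(n_starts - 1L), function(j) {
      v <- b0
      u <- .is_unit(names(v))
      v[!u] <- v[!u] * exp(runif(sum(!u), -log(2), log(2)))
      v[u] <- pmin(0.98, pmax(0.02, v[u] + runif(sum(u), -0.1, 0.1)))
      # keep within wide ranges
      wide <- default_ranges(fit$model_id)
      pmin(wide[, "hi"], pmax(wide[, "lo"], v))
    }))
    r <- tryCatch(
      optimize_model(fit$model_id, boot_spectra[[i]], seed = rep_seeds[i],
                     n_reps = n_reps, stage_runs = c(0L, 0L), maxit = maxit,
                     init = starts),
      error = function(e) NULL)
    if (!is.null(r)) ests[[i]] <- as.numeric(r$params)
  }
  ok <- !vapply(ests, is.null, TRUE)
  if (sum(ok) < max(1L, length(boot_spectra) %/% 2L))
    warning("fewer than half of the bootstrap refits succeeded")
  E <- do.call(rbind, ests[ok])
  colnames(E) <- names(fit$params)
  sds <- apply(E, 2L, sd)
  out <- data.frame(param = names(fit$params), estimate = b0, sd = sds,
                    low = b0 - 1.96 * sds, high = b0 + 1.96 * sds,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_ok") <- sum(ok)
  attr(out, "replicates") <- E
  out
}

# embed an IM2 optimum in IM2_2M space (equal classes, optionally split
# by a factor f), and project an IM2_2M optimum back to IM2 by averaging
# the class rates with weight P
.im2_embed <- function(b, f = 1) {
  c(b[c("s", "N1", "N2", "T")],
    MA1 = max(0.01, unname(b["M1"]) / f), MA2 = max(0.01, unname(b["M2"]) / f),
    MB1 = min(10, unname(b["M1"]) * f), MB2 = min(10, unname(b["M2"]) * f),
    P = 0.5)
}
.im2_project <- function(a) {
  c(a[c("s", "N1", "N2", "T")],
    M1 = unname(a["P"] * a["MA1"] + (1 - a["P"]) * a["MB1"]),
    M2 = unname(a["P"] * a["MA2"] + (1 - a["P"]) * a["MB2"]))
}

#' Likelihood-ratio test for heterogeneous migration (IM2 vs IM2_2M)
#'
#' Fits the direction-specific isolation-with-migration model and its
#' two-class heterogeneous-migration extension to the same observed
#' spectrum on a common likelihood surface (shared engine seed and
#' replicate count), then compares them with a 3-df likelihood-ratio
#' test. Because the models are nested, the richer model is started from
#' embeddings of the null optimum (equal class rates, and rates split by
#' increasing factors) and the null is re-fitted from the projection of
#' the heterogeneous optimum; these alternating refinements repeat until
#' neither model improves, which keeps the statistic from reflecting
#' one-sided optimizer misconvergence rather than heterogeneity.
#'
#' @param obs observed `joint_sfs`.
#' @param seed seed shared by both fits (common random numbers).
#' @param n_reps Monte-Carlo replicates per likelihood evaluation; the
#'   statistic is computed on this surface for both models.
#' @param stage_runs,maxit settings for the initial null fit.
#' @param max_rounds cap on alternating refinement rounds.
#' @return list with `statistic`, `p`, `fit_null`, `fit_alt`.
#' @export
lrt_heterogeneity <- function(obs, seed = 1L, n_reps = 1500L,
                              stage_runs = c(2L, 3L), maxit = 200L,
                              max_rounds = 3L) {
  f0 <- optimize_model("IM2", obs, seed = seed, n_reps = n_reps,
                       stage_runs = stage_runs, maxit = maxit,
                       final_reps = n_reps)
  b <- setNames(as.numeric(f0$params), names(f0$params))
  f1 <- optimize_model("IM2_2M", obs, seed = seed, n_reps = n_reps,
                       stage_runs = c(0L, 0L), maxit = maxit,
                       init = list(.im2_embed(b, 1), .im2_embed(b, 3),
                                   .im2_embed(b, 10)),
                       final_reps = n_reps)
  confirm_maxit <- max(60L, maxit %/% 3L)
  for (rd in seq_len(max_rounds)) {
    improved <- FALSE
    a <- setNames(as.numeric(f1$params), names(f1$params))
    f0b <- optimize_model("IM2", obs, seed = seed, n_reps = n_reps,
                          stage_runs = c(0L, 0L), maxit = confirm_maxit,
                          init = list(.im2_project(a)), final_reps = n_reps)
    if (f0b$loglik > f0$loglik + 0.1) {       # escalate to a full refit
      f0c <- optimize_model("IM2", obs, seed = seed, n_reps = n_reps,
                            stage_runs = c(0L, 0L), maxit = maxit,
                            init = list(setNames(as.numeric(f0b$params),
                                                 names(f0b$params))),
                            final_reps = n_reps)
      f0 <- if (f0c$loglik > f0b$loglik) f0c else f0b
      improved <- TRUE
    }
    b2 <- setNames(as.numeric(f0$params), names(f0$params))
    f1b <- optimize_model("IM2_2M", obs, seed = seed, n_reps = n_reps,
                          stage_runs = c(0L, 0L), maxit = confirm_maxit,
                          init = list(.im2_embed(b2, 1), .im2_embed(b2, 5)),
                          final_reps = n_reps)
    if (f1b$loglik > f1$loglik + 0.1) {
      f1c <- optimize_model("IM2_2M", obs, seed = seed, n_reps = n_reps,
                            stage_runs = c(0L, 0L), maxit = maxit,
                            init = list(setNames(as.numeric(f1b$params),
                                                 names(f1b$params))),
                            final_reps = n_reps)
      f1 <- if (f1c$loglik > f1b$loglik) f1c else f1b
      improved <- TRUE
    }
    if (!improved) break
  }
  l <- suppressWarnings(lrt(f0$loglik, f1$loglik, 3))
  list(statistic = l$statistic, p = l$p, fit_null = f0, fit_alt = f1)
}
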