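## Population specification, response generation and the Monte Carlo
## quality harness: generate data from specified (or estimated)
## parameters, refit and realign each replication, and summarise how well
## the generating factor means are recovered.  The key quality statistic
## is the Pearson correlation between generating and estimated factor
## means computed over groups and averaged over replications; a
## correlation of at least 0.98 is required for a trustworthy ranking.

#' Specify a multi-group generating population
#'
#' Starts from invariant base parameters replicated across groups, then
#' perturbs a seeded random subset of (item, group) cells — the requested
#' percentage of threshold cells and of loading cells — by additive
#' shifts drawn uniformly from the magnitude interval with random sign.
#' A ledger records every perturbation.
#'
#' @param G,P numbers of groups and items.
#' @param base_params list with `lambda`, `tau` (length-P invariant base
#'   values).  Default: loadings evenly spaced on 1.0-1.8 and thresholds
#'   on -1.5..1.5, typical of a mixed-difficulty knowledge test.
#' @param noninv list with `threshold_pct`, `loading_pct` (0-100) and
#'   `magnitude = c(lo, hi)` for the uniform shift magnitude (default
#'   0.3-1.0: detectable but realistic differential item functioning).
#' @param group_means,group_vars generating factor means/variances
#'   (length G; defaults 0 and 1, with group 1 serving as the (0, 1)
#'   reference).
#' @param link `"logit"` or `"probit"`.
#' @param seed RNG seed for cell selection and shift draws.
#' @return object of class `population_spec`: `lambda`/`tau` (P x G),
#'   `alpha`, `psi`, `link`, `ledger` (data frame of perturbations),
#'   `base`, `seed`.
#' @export
make_population <- function(G, P, base_params = NULL,
                            noninv = list(threshold_pct = 0,
                                          loading_pct = 0,
                                          magnitude = c(0.3, 1.0)),
                            group_means = NULL, group_vars = NULL,
                            link = c("logit", "probit"), seed = 1L) {
  link <- match.arg(link)
  G <- as.integer(G); P <- as.integer(P)
  stopifnot(G >= 2, P >= 2)
  base <- base_params %||% list(lambda = seq(1.0, 1.8, length.out = P),
                                tau = seq(-1.5, 1.5, length.out = P))
  stopifnot(length(base$lambda) == P, length(base$tau) == P)
  tp <- noninv$threshold_pct %||% 0
  lp <- noninv$loading_pct %||% 0
  mag <- noninv$magnitude %||% c(0.3, 1.0)
  stopifnot(tp >= 0, tp <= 100, lp >= 0, lp <= 100)
  alpha <- group_means %||% rep(0, G)
  psi <- group_vars %||% rep(1, G)
  stopifnot(length(alpha) == G, length(psi) == G, all(psi > 0))
  groups <- paste0("g", seq_len(G))
  items <- paste0("Y", seq_len(P))
  lambda <- matrix(base$lambda, P, G, dimnames = list(items, groups))
  tau <- matrix(base$tau, P, G, dimnames = list(items, groups))
  n_thr <- round(tp / 100 * P * G)
  n_lod <- round(lp / 100 * P * G)
  if (n_thr > P * G || n_lod > P * G)
    stop("non-invariance percentage infeasible for the item x group grid",
         call. = FALSE)
  ledger <- with_seed(seed, {
    led <- list()
    if (n_thr > 0) {
      cells <- sample.int(P * G, n_thr)
      delta <- stats::runif(n_thr, mag[1], mag[2]) *
        sample(c(-1, 1), n_thr, replace = TRUE)
      tau[cells] <- tau[cells] + delta
      led$thr <- data.frame(family = "threshold",
                            item = items[(cells - 1) %% P + 1],
                            group = groups[(cells - 1) %/% P + 1],
                            delta = delta)
    }
    if (n_lod > 0) {
      cells <- sample.int(P * G, n_lod)
      delta <- stats::runif(n_lod, mag[1], mag[2]) *
        sample(c(-1, 1), n_lod, replace = TRUE)
      lambda[cells] <- lambda[cells] + delta
      led$lod <- data.frame(family = "loading",
                            item = items[(cells - 1) %% P + 1],
                            group = groups[(cells - 1) %/% P + 1],
                            delta = delta)
    }
    do.call(rbind, led) %||%
      data.frame(family = character(), item = character(),
                 group = character(), delta = numeric())
  })
  rownames(ledger) <- NULL
  structure(list(G = G, P = P, lambda = lambda, tau = tau,
                 alpha = stats::setNames(alpha, groups),
                 psi = stats::setNames(psi, groups),
                 link = link, ledger = ledger, base = base, seed = seed,
                 groups = groups, items = items),
            class = "population_spec")
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf("population_spec: %d groups x %d items (%s link)\n",
              x$G, x$P, x$link))
  cat(sprintf("perturbed cells: %d thresholds, %d loadings\n",
              sum(x$ledger$family == "threshold"),
              sum(x$ledger$family == "loading")))
  cat(sprintf("factor means in [%.2f, %.2f], variances in [%.2f, %.2f]\n",
              min(x$alpha), max(x$alpha), min(x$psi), max(x$psi)))
  invisible(x)
}

#' Promote an alignment result to a generating population
#'
#' The estimated aligned parameters and group distributions can be saved
#' and used for data generation, closing the loop between a real-data
#' analysis and its Monte Carlo quality check.
#'
#' @param result an [align()] result.
#' @return a `population_spec`.
#' @export
as_population <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  structure(list(G = ncol(result$lambda), P = nrow(result$lambda),
                 lambda = result$lambda, tau = result$tau,
                 alpha = result$alpha, psi = result$psi,
                 link = result$link,
                 ledger = data.frame(family = character(),
                                     item = character(),
                                     group = character(),
                                     delta = numeric()),
                 base = NULL, seed = NA_integer_,
                 groups = result$groups, items = result$items),
            class = "population_spec")
}

#' Generate binary responses from a population
#'
#' Per respondent: draw eta ~ N(alpha_g, psi_g), then each item is
#' Bernoulli with probability [threshold_model_prob()] at the group's
#' parameters.  Fully reproducible under the seed.
#'
#' @param pop a [make_population()] spec.
#' @param group_sizes integer vector of length G (all >= 1).
#' @param seed RNG seed.
#' @return a [response_data()] object with `sum(group_sizes)` rows.
#' @export
generate_responses <- function(pop, group_sizes, seed = 1L) {
  stopifnot(inherits(pop, "population_spec"),
            length(group_sizes) == pop$G, all(group_sizes >= 1))
  with_seed(seed, {
    blocks <- lapply(seq_len(pop$G), function(g) {
      n <- group_sizes[g]
      eta <- stats::rnorm(n, pop$alpha[g], sqrt(pop$psi[g]))
      pr <- link_cdf(pop$link)(tcrossprod(eta, pop$lambda[, g]) -
                                 matrix(pop$tau[, g], n, pop$P,
                                        byrow = TRUE))
      matrix(as.numeric(stats::runif(n * pop$P) < pr), n, pop$P)
    })
    y <- do.call(rbind, blocks)
    colnames(y) <- pop$items
    response_data(y, rep(pop$groups, group_sizes), items = pop$items)
  })
}

#' Mean correlation between true and estimated factor means
#'
#' Pearson correlation across groups within each replication, then the
#' arithmetic mean over replications.
#'
#' @param true_means length-G vector of generating means.
#' @param estimated matrix (replications x G) or a single vector.
#' @return the average correlation.
#' @export
mean_correlation <- function(true_means, estimated) {
  if (is.null(dim(estimated))) estimated <- matrix(estimated, nrow = 1)
  stopifnot(ncol(estimated) == length(true_means), length(true_means) >= 3)
  if (stats::sd(true_means) == 0)
    stop("correlation undefined: generating means have zero variance",
         call. = FALSE)
  r <- apply(estimated, 1, function(e) {
    if (stats::sd(e) == 0)
      stop("correlation undefined: estimated means have zero variance",
           call. = FALSE)
    stats::cor(true_means, e)
  })
  mean(r)
}

#' Monte Carlo assessment of alignment quality
#'
#' Per replication: generate responses, fit the configural model, align,
#' and record the estimated factor means, variances and aligned
#' parameters.  Summaries include the correlation between generating and
#' estimated factor means (over groups, averaged over replications) with
#' the 0.98 near-perfect-correlation verdict, per-group mean bias, and
#' parameter bias/RMSE (and 95% coverage when `compute_se = TRUE`).
#' Failed replications are dropped with a logged count; more than 20%
#' failures is an error.
#'
#' @param pop a [make_population()] spec.
#' @param group_sizes integer vector of group sizes.
#' @param n_reps number of replications (>= 1).
#' @param options [alignment_options()] for each realignment.
#' @param quad [quadrature_spec()].
#' @param seed master seed; every source of randomness derives from it.
#' @param compute_se also compute delta-method SEs per replication and
#'   95% coverage of the group means (slower).
#' @return object of class `mc_summary`.
#' @export
run_monte_carlo <- function(pop, group_sizes, n_reps = 100L,
                            options = alignment_options(),
                            quad = quadrature_spec(), seed = 1L,
                            compute_se = FALSE) {
  stopifnot(inherits(pop, "population_spec"), n_reps >= 1)
  seeds <- derive_seeds(seed, 2L * n_reps)
  est_alpha <- matrix(NA_real_, n_reps, pop$G)
  est_psi <- matrix(NA_real_, n_reps, pop$G)
  est_lambda <- array(NA_real_, c(n_reps, pop$P, pop$G))
  est_tau <- array(NA_real_, c(n_reps, pop$P, pop$G))
  cover <- matrix(NA, n_reps, pop$G)
  ok <- logical(n_reps)
  failures <- character(0)
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      dat <- generate_responses(pop, group_sizes, seed = seeds[2 * r - 1])
      cf <- fit_configural(dat, quad, pop$link, se = compute_se)
      opt_r <- options; opt_r$seed <- seeds[2 * r]
      ar <- align(cf, opt_r)
      list(cf = cf, ar = ar)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("rep %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    ok[r] <- TRUE
    gi <- match(pop$groups, res$ar$groups)  # align by label, not position
    est_alpha[r, ] <- res$ar$alpha[gi]
    est_psi[r, ] <- res$ar$psi[gi]
    est_lambda[r, , ] <- res$ar$lambda[, gi]
    est_tau[r, , ] <- res$ar$tau[, gi]
    if (compute_se) {
      ses <- aligned_standard_errors(res$ar, res$cf)
      lo <- (res$ar$alpha - 1.959964 * ses$se_alpha)[gi]
      hi <- (res$ar$alpha + 1.959964 * ses$se_alpha)[gi]
      cov_r <- pop$alpha >= lo & pop$alpha <= hi
      cov_r[match(res$ar$groups[res$ar$ref_group], pop$groups)] <- NA
      cover[r, ] <- cov_r
    }
  }
  if (mean(!ok) > 0.20)
    stop(sprintf("more than 20%% of replications failed (%d of %d):\n%s",
                 sum(!ok), n_reps, paste(failures, collapse = "\n")),
         call. = FALSE)
  ea <- est_alpha[ok, , drop = FALSE]
  corr <- mean_correlation(pop$alpha, ea)
  bias_alpha <- colMeans(ea) - pop$alpha
  rmse_alpha <- sqrt(colMeans(sweep(ea, 2, pop$alpha)^2))
  bias_psi <- colMeans(est_psi[ok, , drop = FALSE]) - pop$psi
  mean_lam <- apply(est_lambda[ok, , , drop = FALSE], c(2, 3), mean)
  mean_tau <- apply(est_tau[ok, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(n_reps = n_reps, n_ok = sum(ok), failures = failures,
         mean_correlation = corr,
         reliable = corr >= 0.98,
         bias_alpha = stats::setNames(bias_alpha, pop$groups),
         rmse_alpha = stats::setNames(rmse_alpha, pop$groups),
         bias_psi = stats::setNames(bias_psi, pop$groups),
         bias_lambda = mean_lam - pop$lambda,
         bias_tau = mean_tau - pop$tau,
         coverage_alpha = if (compute_se)
           colMeans(cover[ok, , drop = FALSE], na.rm = TRUE),
         est_alpha = est_alpha, est_psi = est_psi,
         true_alpha = pop$alpha, true_psi = pop$psi, seed = seed),
    class = "mc_summary")
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte Carlo summary: %d/%d replications converged\n",
              x$n_ok, x$n_reps))
  cat(sprintf("mean correlation of true vs estimated factor means: %.4f\n",
              x$mean_correlation))
  cat(if (x$reliable)
    "  >= 0.98: near-perfect, factor mean ranking trustworthy\n"
    else
      "  < 0.98: below the near-perfect bar, ranking not trustworthy\n")
  cat(sprintf("group-mean bias range: [%.3f, %.3f]; RMSE range: [%.3f, %.3f]\n",
              min(x$bias_alpha), max(x$bias_alpha),
              min(x$rmse_alpha), max(x$rmse_alpha)))
  if (!is.null(x$coverage_alpha))
    cat(sprintf("95%% coverage of group means (non-reference): %.3f\n",
                mean(x$coverage_alpha, na.rm = TRUE)))
  invisible(x)
}
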