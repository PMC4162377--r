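## Post-alignment inference: which item parameters are invariant in which
## groups, how much non-invariance there is overall, and the factor-mean
## ranking with pairwise significance.

## variance of the difference of two aligned parameters, using the full
## delta-method covariance when available
pair_var <- function(se_vec, Vsub = NULL, g, h) {
  v <- se_vec[g]^2 + se_vec[h]^2
  if (!is.null(Vsub)) v <- v - 2 * Vsub[g, h]
  max(v, 1e-12)
}

## invariant-set search for one item x parameter family.
## theta, se: length-G; Vsub: optional G x G covariance; N: group sizes.
## 1) all pairwise z-tests; 2) greedy largest mutually-non-significant
## set (ties: largest total N, then lexicographic label order);
## 3) iterative refinement against the inverse-variance-weighted set mean.
invariant_set_one <- function(theta, se, Vsub, N, labels, alpha_level) {
  G <- length(theta)
  pz <- matrix(1, G, G)
  for (g in seq_len(G - 1)) for (h in (g + 1):G) {
    z <- (theta[g] - theta[h]) / sqrt(pair_var(se, Vsub, g, h))
    pz[g, h] <- pz[h, g] <- 2 * stats::pnorm(-abs(z))
  }
  nonsig <- pz >= alpha_level
  diag(nonsig) <- TRUE
  ord <- order(-colSums(nonsig), labels)
  candidates <- lapply(seq_len(G), function(seed) {
    S <- seed
    for (g in ord) {
      if (g %in% S) next
      if (all(nonsig[g, S])) S <- c(S, g)
    }
    sort(S)
  })
  candidates <- unique(candidates)
  sizes <- vapply(candidates, length, 0L)
  totN <- vapply(candidates, function(S) sum(N[S]), 0)
  key <- order(-sizes, -totN,
               vapply(candidates, function(S)
                 paste(labels[S], collapse = " "), ""))
  S <- candidates[[key[1]]]
  ## refinement: test each group against the weighted mean of the set
  for (iter in seq_len(50L)) {
    w <- 1 / pmax(se[S]^2, 1e-12)
    mu <- sum(w * theta[S]) / sum(w)
    pv <- 2 * stats::pnorm(-abs((theta - mu) / pmax(se, 1e-6)))
    drop <- S[pv[S] < alpha_level]
    add <- setdiff(which(pv >= alpha_level), S)
    S2 <- sort(union(setdiff(S, drop), add))
    if (length(S2) == 0) S2 <- S[which.max(pv[S])]  # never empty the set
    if (identical(S2, S)) break
    S <- S2
  }
  list(invariant = S, flagged = setdiff(seq_len(G), S), pz = pz,
       p_vs_set = {
     w <- 1 / pmax(se[S]^2, 1e-12)
     mu <- sum(w * theta[S]) / sum(w)
     2 * stats::pnorm(-abs((theta - mu) / pmax(se, 1e-6)))
   })
}

#' Detect invariant group sets per item parameter
#'
#' For every item and parameter family (threshold, loading), partitions
#' the groups into an invariant set and a flagged (significantly
#' non-invariant) set, using all pairwise z-tests on aligned-parameter
#' differences followed by an iterative refinement against the
#' inverse-variance-weighted mean of the current invariant set.  With
#' G = 2 this reduces to the single pairwise test.
#'
#' @param result an [align()] result.
#' @param ses an [aligned_standard_errors()] result.
#' @param alpha_level per-test significance level (default 0.01, no
#'   multiplicity correction).
#' @return object of class `invariance_flags`: for each family a P x G
#'   logical `flagged` matrix, the invariant sets, and pairwise p-values.
#' @export
detect_invariant_sets <- function(result, ses, alpha_level = 0.01) {
  stopifnot(inherits(result, "alignment_result"),
            alpha_level > 0, alpha_level < 1)
  P <- nrow(result$lambda); G <- ncol(result$lambda)
  N <- result$group_sizes; labels <- result$groups
  fam <- list(
    threshold = list(theta = result$tau, se = ses$se_tau,
                     idx = ses$index$tau),
    loading = list(theta = result$lambda, se = ses$se_lambda,
                   idx = ses$index$lambda))
  out <- lapply(names(fam), function(fn) {
    fobj <- fam[[fn]]
    flagged <- matrix(FALSE, P, G, dimnames = dimnames(result$lambda))
    sets <- vector("list", P)
    for (p in seq_len(P)) {
      Vsub <- NULL
      if (!is.null(ses$vcov)) {
        rows <- fobj$idx[p + (seq_len(G) - 1) * P]
        Vsub <- ses$vcov[rows, rows, drop = FALSE]
      }
      r <- invariant_set_one(fobj$theta[p, ], fobj$se[p, ], Vsub, N,
                             labels, alpha_level)
      flagged[p, r$flagged] <- TRUE
      sets[[p]] <- list(invariant = labels[r$invariant],
                        flagged = labels[r$flagged],
                        p_vs_set = stats::setNames(r$p_vs_set, labels))
    }
    names(sets) <- result$items
    list(flagged = flagged, sets = sets)
  })
  names(out) <- names(fam)
  structure(list(threshold = out$threshold, loading = out$loading,
                 alpha_level = alpha_level, groups = labels,
                 items = result$items),
            class = "invariance_flags")
}

#' @export
print.invariance_flags <- function(x, ...) {
  cat(sprintf("invariance flags (per-test alpha = %g); flagged groups in parentheses\n",
              x$alpha_level))
  for (fn in c("threshold", "loading")) {
    cat("\n", fn, "s:\n", sep = "")
    fl <- x[[fn]]$flagged
    for (p in seq_along(x$items)) {
      marks <- ifelse(fl[p, ], paste0("(", x$groups, ")"), x$groups)
      cat(sprintf("  %-6s %s\n", x$items[p], paste(marks, collapse = " ")))
    }
  }
  invisible(x)
}

#' Summarise non-invariance rates against the 25% rule of thumb
#'
#' Percentage of flagged (item, group) cells per parameter family, their
#' simple average, and the verdict: alignment results are regarded as
#' trustworthy when the average non-invariance is at most 25%; above
#' that, a Monte Carlo check ([run_monte_carlo()]) is recommended.
#'
#' @param flags a [detect_invariant_sets()] result.
#' @return list of class `noninvariance_summary` with `threshold_pct`,
#'   `loading_pct`, `average_pct`, `verdict`.
#' @export
noninvariance_summary <- function(flags) {
  stopifnot(inherits(flags, "invariance_flags"))
  thr <- 100 * mean(flags$threshold$flagged)
  lod <- 100 * mean(flags$loading$flagged)
  avg <- (thr + lod) / 2
  structure(list(threshold_pct = thr, loading_pct = lod, average_pct = avg,
                 verdict = if (avg <= 25) "trustworthy"
                           else "run Monte Carlo"),
            class = "noninvariance_summary")
}

#' @export
print.noninvariance_summary <- function(x, ...) {
  cat(sprintf("non-invariant cells: thresholds %.1f%%, loadings %.1f%%, average %.1f%%\n",
              x$threshold_pct, x$loading_pct, x$average_pct))
  cat("verdict:", x$verdict,
      if (x$verdict == "trustworthy") "(average <= 25%)"
      else "(average > 25%; check mean recovery by simulation)", "\n")
  invisible(x)
}

#' Rank groups by estimated factor mean with pairwise significance
#'
#' Orders groups by estimated factor mean (descending; ties broken by
#' group label) and, for each group, lists the groups whose mean is
#' significantly smaller by a one-sided z-test on the signed difference
#' (covariance between aligned means used when available).
#'
#' @param result an [align()] result.
#' @param ses an [aligned_standard_errors()] result.
#' @param alpha_level per-comparison level (default 0.05).
#' @param adjust `"none"` (default) or `"bonferroni"` over the
#'   G(G-1)/2 pairs.
#' @return data frame of class `mean_ranking` with columns `rank`,
#'   `group`, `mean`, `se`, `smaller` (space-separated group labels).
#' @export
factor_mean_ranking <- function(result, ses, alpha_level = 0.05,
                                adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(result, "alignment_result"),
            alpha_level > 0, alpha_level < 1)
  G <- length(result$alpha)
  a <- if (adjust == "bonferroni") alpha_level / n_group_pairs(G)
       else alpha_level
  Vsub <- if (!is.null(ses$vcov))
    ses$vcov[ses$index$alpha, ses$index$alpha, drop = FALSE]
  ord <- order(-result$alpha, result$groups)
  smaller <- character(G)
  for (i in seq_len(G)) {
    g <- ord[i]
    below <- ord[seq_len(G) > i]
    sig <- below[vapply(below, function(h) {
      z <- (result$alpha[g] - result$alpha[h]) /
        sqrt(pair_var(ses$se_alpha, Vsub, g, h))
      stats::pnorm(z, lower.tail = FALSE) < a
    }, TRUE)]
    smaller[i] <- paste(result$groups[sig], collapse = " ")
  }
  out <- data.frame(rank = seq_len(G), group = result$groups[ord],
                    mean = unname(result$alpha[ord]),
                    se = unname(ses$se_alpha[ord]),
                    smaller = smaller, stringsAsFactors = FALSE)
  class(out) <- c("mean_ranking", "data.frame")
  attr(out, "alpha_level") <- alpha_level
  out
}

#' @export
print.mean_ranking <- function(x, digits = 3, ...) {
  cat(sprintf("factor mean ranking (one-sided pairwise tests, alpha = %g)\n",
              attr(x, "alpha_level")))
  y <- as.data.frame(x)
  y$mean <- round(y$mean, digits); y$se <- round(y$se, digits)
  names(y)[names(y) == "smaller"] <- "significantly smaller"
  print(y, row.names = FALSE)
  invisible(x)
}
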