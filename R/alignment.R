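## The alignment engine: transform configural estimates under candidate
## group factor distributions, score non-invariance with a component loss
## function accumulated over all items and group pairs, and minimize the
## total loss over the free factor means and variances.
##
## Likelihood-preserving transformation.  With the threshold convention
## P(y=1|eta) = F(lambda*eta - tau) and eta ~ N(alpha, psi),
##     lambda1 = lambda0 / sqrt(psi)
##     tau1    = tau0 + alpha * lambda0 / sqrt(psi)
## reproduces the configural likelihood exactly for every (alpha, psi):
## substituting eta = alpha + sqrt(psi) * theta, theta ~ N(0,1), gives
## lambda1*eta - tau1 = lambda0*theta - tau0 pointwise.  (Thresholds are
## negated intercepts, so the intercept update nu1 = nu0 - alpha*lambda1
## carries a plus sign here.)

#' Options controlling the alignment optimization
#'
#' @param epsilon CLF smoothing constant (> 0, default 0.0001).
#' @param clf component-loss form: `"fourth-root"` (default),
#'   f(x) = (x^2 + eps)^(1/4), a smooth surrogate of sqrt(|x|) whose
#'   concavity in |x| concentrates non-invariance in few large
#'   differences; or `"square-root"`, f(x) = (x^2 + eps)^(1/2).
#' @param weights pairwise group weights: `"sqrt-product"` (default),
#'   w = sqrt(N_g1 * N_g2), so pairs of large (precisely estimated)
#'   groups dominate; or `"unit"`.
#' @param identification `"fixed"` (reference group pinned to mean 0,
#'   variance 1; default) or `"product"` (product of variances = 1, mean
#'   of the first group 0).
#' @param difference_scaling `"lambda-geomean"` (default): each pairwise
#'   *loading* difference entering the CLF is divided by the geometric
#'   mean of the two groups' aligned loadings for that item, making the
#'   loading term invariant to the aligned-parameter scale (threshold
#'   differences enter raw; they are location-driven and not subject to
#'   the scale degeneracy).  `"none"` applies the CLF to raw loading
#'   differences too; that form is degenerate on noisy estimates
#'   (inflating all factor variances shrinks every aligned loading toward
#'   zero, which a concave CLF rewards) and is provided for study only.
#' @param ref_group index or label of the reference group (default:
#'   first).
#' @param n_starts multistart count (>= 1, default 30; the loss surface
#'   can be multimodal).
#' @param sd_alpha,sd_logpsi standard deviations of the seeded normal
#'   perturbations applied to the non-reference starting values.
#' @param tol optimizer tolerance on the loss.
#' @param seed seed for the multistart perturbations.
#' @return an `alignment_options` list.
#' @export
alignment_options <- function(epsilon = 1e-4,
                              clf = c("fourth-root", "square-root"),
                              weights = c("sqrt-product", "unit"),
                              identification = c("fixed", "product"),
                              difference_scaling = c("lambda-geomean",
                                                     "none"),
                              ref_group = 1L, n_starts = 30L,
                              sd_alpha = 0.5, sd_logpsi = 0.3,
                              tol = 1e-8, seed = 1L) {
  stopifnot(epsilon > 0, n_starts >= 1)
  structure(list(epsilon = epsilon, clf = match.arg(clf),
                 weights = match.arg(weights),
                 identification = match.arg(identification),
                 difference_scaling = match.arg(difference_scaling),
                 ref_group = ref_group, n_starts = as.integer(n_starts),
                 sd_alpha = sd_alpha, sd_logpsi = sd_logpsi,
                 tol = tol, seed = as.integer(seed)),
            class = "alignment_options")
}

#' Component loss function
#'
#' Even, strictly increasing in |x|, applied to every pairwise difference
#' of aligned item parameters.  Default fourth-root form
#' `(x^2 + epsilon)^(1/4)`; `"square-root"` gives `(x^2 + epsilon)^(1/2)`.
#'
#' @param x parameter difference(s).
#' @param epsilon smoothing constant (> 0).
#' @param form `"fourth-root"` or `"square-root"`.
#' @return loss values, same shape as `x`.
#' @examples
#' clf(0)    # epsilon^(1/4) = 0.1 at the default epsilon
#' clf(1)    # 1.0000250
#' @export
clf <- function(x, epsilon = 1e-4, form = c("fourth-root", "square-root")) {
  form <- match.arg(form)
  stopifnot(epsilon > 0)
  if (form == "fourth-root") sqrt(sqrt(x * x + epsilon))
  else sqrt(x * x + epsilon)
}

clf_grad <- function(x, epsilon, form) {
  q <- sqrt(x * x + epsilon)
  if (form == "fourth-root") 0.5 * x / (q * sqrt(q)) else x / q
}

#' Pairwise group weights for the total loss
#'
#' @param group_sizes vector of group sizes N_g (all >= 1).
#' @param mode `"sqrt-product"` (w = sqrt(N_g1 N_g2)) or `"unit"`.
#' @return symmetric G x G matrix (diagonal unused).
#' @export
pair_weights <- function(group_sizes, mode = c("sqrt-product", "unit")) {
  mode <- match.arg(mode)
  stopifnot(all(group_sizes >= 1))
  G <- length(group_sizes)
  if (mode == "unit") matrix(1, G, G)
  else tcrossprod(sqrt(group_sizes))
}

#' Alignment transformation of configural parameters
#'
#' Maps configural-scale loadings and thresholds to the scale implied by
#' group factor distributions N(alpha_g, psi_g):
#' `lambda1 = lambda0 / sqrt(psi)`,
#' `tau1 = tau0 + alpha * lambda0 / sqrt(psi)`.
#' For every (alpha, psi) the transformed parameters combined with
#' eta ~ N(alpha, psi) reproduce the configural likelihood exactly; at
#' alpha = 0, psi = 1 the transform is the identity.
#'
#' @param lambda0,tau0 configural loadings/thresholds: P x G matrices (or
#'   vectors for a single group).
#' @param alpha,psi factor means and variances, length G (psi > 0).
#' @return list with matrices `lambda` and `tau` on the aligned scale.
#' @export
align_transform <- function(lambda0, tau0, alpha, psi) {
  if (any(psi <= 0)) stop("factor variances must be strictly positive",
                          call. = FALSE)
  lambda0 <- as.matrix(lambda0); tau0 <- as.matrix(tau0)
  s <- rep(1 / sqrt(psi), each = nrow(lambda0))
  a <- rep(alpha, each = nrow(lambda0))
  lambda1 <- lambda0 * s
  tau1 <- tau0 + a * lambda0 * s
  dimnames(lambda1) <- dimnames(tau1) <- dimnames(lambda0)
  list(lambda = lambda1, tau = tau1)
}

## inverse of align_transform: push invariant parameters onto the
## configural scale implied by (alpha, psi); used to build analytic
## fixtures and to promote populations
align_transform_inverse <- function(lambda1, tau1, alpha, psi) {
  if (any(psi <= 0)) stop("factor variances must be strictly positive",
                          call. = FALSE)
  lambda1 <- as.matrix(lambda1); tau1 <- as.matrix(tau1)
  s <- rep(sqrt(psi), each = nrow(lambda1))
  a <- rep(alpha, each = nrow(lambda1))
  lambda0 <- lambda1 * s
  tau0 <- tau1 - a * lambda1
  dimnames(lambda0) <- dimnames(tau0) <- dimnames(lambda1)
  list(lambda = lambda0, tau = tau0)
}

## smallest loading geometric mean used in difference scaling; below this
## the scale is floored (and its derivative dropped) to keep the loss
## finite when an optimizer visits near-zero loadings
SCALE_FLOOR <- 0.05

## pairwise difference array: D[p,g,h] = X[p,g] - X[p,h]
pair_diffs <- function(X) {
  P <- nrow(X); G <- ncol(X)
  A <- array(X, c(P, G, G))
  A - aperm(A, c(1, 3, 2))
}

## pairwise scale array S[p,g,h] = sqrt(|lambda1_pg * lambda1_ph|)
## (floored), or all-ones when scaling is off
pair_scales <- function(lam1, scaling) {
  P <- nrow(lam1); G <- ncol(lam1)
  if (scaling == "none")
    return(list(S = array(1, c(P, G, G)), active = array(0, c(P, G, G))))
  A <- array(abs(lam1), c(P, G, G))
  S <- sqrt(A * aperm(A, c(1, 3, 2)))
  list(active = array(as.numeric(S > SCALE_FLOOR), c(P, G, G)),
       S = pmax(S, SCALE_FLOOR))
}

## weighted CLF terms for both families: P x G x G arrays (zero diagonal,
## symmetric in the unordered pair, so sums over g<h use upper.tri).
## Loading differences are scale-normalized per the options; threshold
## differences always enter raw.
loss_terms <- function(lam1, tau1, W, options) {
  P <- nrow(lam1); G <- ncol(lam1)
  sc <- pair_scales(lam1, options$difference_scaling)
  Wfull <- array(rep(W, each = P), c(P, G, G))
  for (g in seq_len(G)) Wfull[, g, g] <- 0
  list(TL = clf(pair_diffs(lam1) / sc$S, options$epsilon, options$clf) * Wfull,
       TT = clf(pair_diffs(tau1), options$epsilon, options$clf) * Wfull)
}

#' Total alignment loss (simplicity function)
#'
#' Accumulates the component loss of every pairwise difference of aligned
#' loadings and aligned thresholds over all items and unordered group
#' pairs, weighted by the pairwise group weights:
#' `F = sum_p sum_{g1<g2} w_{g1,g2} [ f(dlambda_p,g1g2) +
#' f(dtau_p,g1g2) ]`, where the differences are divided by the geometric
#' mean of the two aligned loadings under the default difference scaling
#' (see [alignment_options()]), or raw under `"none"`.
#'
#' @param lambda0,tau0 configural-scale parameter matrices (P x G).
#' @param alpha,psi candidate group factor means/variances (psi > 0).
#' @param weights G x G weight matrix (default from [pair_weights()] with
#'   unit sizes).
#' @param options [alignment_options()] (CLF form, epsilon and difference
#'   scaling are used).
#' @return the scalar loss `F`, with attributes `loading` and
#'   `threshold` holding the two family subtotals.
#' @export
total_loss <- function(lambda0, tau0, alpha, psi, weights = NULL,
                       options = alignment_options()) {
  lambda0 <- as.matrix(lambda0); tau0 <- as.matrix(tau0)
  G <- ncol(lambda0)
  weights <- weights %||% matrix(1, G, G)
  al <- align_transform(lambda0, tau0, alpha, psi)
  lt <- loss_terms(al$lambda, al$tau, weights, options)
  sel <- rep(upper.tri(matrix(0, G, G)), each = nrow(lambda0))
  l_load <- sum(lt$TL[sel]); l_thr <- sum(lt$TT[sel])
  structure(l_load + l_thr, loading = l_load, threshold = l_thr)
}

## loss and analytic gradient wrt the free vector x used by align().
## With scaled differences d = (x_g - x_h)/S, S = sqrt(|lam1_g lam1_h|):
##   dS/dlam1_g = S/(2 lam1_g)  (any sign of lam1_g), so
##   d(dL)/dlam1_g = 1/S - dL/(2 lam1_g),  d(dT)/dlam1_g = -dT/(2 lam1_g),
##   d(dT)/dtau1_g = 1/S.
## The derivative terms through S are dropped where the floor is active.
loss_engine <- function(lambda0, tau0, weights, options) {
  P <- nrow(lambda0); G <- ncol(lambda0)
  eps <- options$epsilon; form <- options$clf
  scaling <- options$difference_scaling
  sel <- rep(upper.tri(matrix(0, G, G)), each = P)
  W0 <- weights; diag(W0) <- 0
  Wfull <- array(rep(W0, each = P), c(P, G, G))

  function(alpha, psi, want_grad = TRUE) {
    s <- 1 / sqrt(psi)
    lam1 <- sweep(lambda0, 2, s, `*`)
    tau1 <- tau0 + sweep(lambda0, 2, alpha * s, `*`)
    sc <- pair_scales(lam1, scaling)
    DL <- pair_diffs(lam1) / sc$S
    DT <- pair_diffs(tau1)
    fL <- clf(DL, eps, form); fT <- clf(DT, eps, form)
    val <- sum(((fL + fT) * Wfull)[sel])
    if (!want_grad) return(list(value = val))
    gL <- clf_grad(DL, eps, form) * Wfull   # w * f'(dL), per (p,g,h)
    gT <- clf_grad(DT, eps, form) * Wfull
    cL <- rowSums(gL / sc$S, dims = 2)      # dF/dlam1 direct part
    cT <- rowSums(gT, dims = 2)             # dF/dtau1
    if (scaling != "none") {
      ## scale-derivative part of dF/dlam1: -f'(dL) dL / (2 lam1)
      extra <- rowSums(gL * DL * sc$active, dims = 2)
      cL <- cL - extra / (2 * lam1)
    }
    ## chain to (alpha_g, log psi_g):
    ##   dlam1/dlogpsi = -lam1/2;  dtau1/dalpha = lambda0*s;
    ##   dtau1/dlogpsi = -alpha*lambda0*s/2
    lam0s <- sweep(lambda0, 2, s, `*`)
    g_alpha <- colSums(cT * lam0s)
    g_logpsi <- colSums(cL * (-0.5 * lam1)) +
      colSums(cT * sweep(-0.5 * lam0s, 2, alpha, `*`))
    list(value = val, g_alpha = g_alpha, g_logpsi = g_logpsi)
  }
}

#' Align a configural fit
#'
#' Minimizes the total loss [total_loss()] over the free group factor
#' means and variances (the reference entries pinned according to the
#' identification), by seeded multistart quasi-Newton optimization on
#' (alpha, log psi).  The first start is the configural point (all means
#' 0, variances 1); the remaining starts perturb it.  The lowest-loss
#' solution is returned (ties broken by the earliest start).
#'
#' @param fit a `configural_fit` (from [fit_configural()] or
#'   [configural_fit()]).
#' @param options [alignment_options()].
#' @return object of class `alignment_result`: `alpha`, `psi`, aligned
#'   `lambda`/`tau`, `loss` (+ family subtotals), `weights`, `options`,
#'   per-start `diagnostics`, and the configural inputs.
#' @export
align <- function(fit, options = alignment_options()) {
  stopifnot(inherits(fit, "configural_fit"))
  lambda0 <- fit$lambda; tau0 <- fit$tau
  P <- nrow(lambda0); G <- ncol(lambda0)
  if (G < 2) stop("alignment needs at least 2 groups", call. = FALSE)
  W <- pair_weights(fit$group_sizes, options$weights)
  eng <- loss_engine(lambda0, tau0, W, options)

  ref <- options$ref_group
  if (is.character(ref)) ref <- match(ref, fit$groups)
  if (is.na(ref) || ref < 1 || ref > G)
    stop("invalid reference group", call. = FALSE)
  free <- setdiff(seq_len(G), ref)

  if (options$identification == "fixed") {
    expand <- function(x) {
      alpha <- numeric(G); lp <- numeric(G)
      alpha[free] <- x[seq_len(G - 1)]
      lp[free] <- x[G - 1 + seq_len(G - 1)]
      list(alpha = alpha, psi = exp(lp))
    }
    shrink_grad <- function(e) c(e$g_alpha[free],
                                 e$g_logpsi[free])
    npar <- 2 * (G - 1)
  } else {
    ## product identification: prod(psi) = 1 via logpsi_G = -sum(others);
    ## mean of the first group pinned to 0
    expand <- function(x) {
      alpha <- numeric(G); lp <- numeric(G)
      alpha[free] <- x[seq_len(G - 1)]
      lp[seq_len(G - 1)] <- x[G - 1 + seq_len(G - 1)]
      lp[G] <- -sum(lp[seq_len(G - 1)])
      list(alpha = alpha, psi = exp(lp))
    }
    shrink_grad <- function(e) c(e$g_alpha[free],
                                 e$g_logpsi[seq_len(G - 1)] - e$g_logpsi[G])
    npar <- 2 * (G - 1)
  }

  objective <- make_objective(function(x) {
    th <- expand(x)
    e <- eng(th$alpha, th$psi, want_grad = TRUE)
    list(value = e$value, gradient = shrink_grad(e))
  })

  starts <- matrix(0, options$n_starts, npar)
  if (options$n_starts > 1) {
    pert <- with_seed(options$seed, {
      cbind(matrix(stats::rnorm((options$n_starts - 1) * (G - 1),
                                sd = options$sd_alpha),
                   options$n_starts - 1, G - 1),
            matrix(stats::rnorm((options$n_starts - 1) * (G - 1),
                                sd = options$sd_logpsi),
                   options$n_starts - 1, G - 1))
    })
    starts[-1, ] <- pert
  }

  ## box the free parameters: means in [-10, 10], log variances in
  ## [-5, 5]; far outside any plausible aligned solution, but prevents
  ## line searches wandering into degenerate territory
  lower <- c(rep(-10, G - 1), rep(-5, G - 1))
  upper <- c(rep(10, G - 1), rep(5, G - 1))
  runs <- vector("list", options$n_starts)
  for (sidx in seq_len(options$n_starts)) {
    runs[[sidx]] <- tryCatch(
      stats::optim(starts[sidx, ], objective$fn, objective$gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, factr = 1e6)),
      error = function(e) list(value = Inf, convergence = 99L,
                               message = conditionMessage(e)))
  }
  losses <- vapply(runs, function(r) r$value, 0)
  if (all(!is.finite(losses)))
    stop("alignment optimizer failed in every start; per-start diagnostics:\n",
         paste(sprintf("  start %d: %s", seq_along(runs),
                       vapply(runs, function(r) r$message %||% "Inf loss", "")),
               collapse = "\n"), call. = FALSE)
  best <- which.min(losses)          # first-found on ties
  xhat <- runs[[best]]$par
  ## never worse than the unperturbed configural start
  base <- objective$fn(starts[1, ])
  if (losses[best] > base + 1e-12) {
    xhat <- starts[1, ]; best <- 1L
  }
  th <- expand(xhat)
  al <- align_transform(lambda0, tau0, th$alpha, th$psi)
  fin <- eng(th$alpha, th$psi, want_grad = FALSE)$value
  lv <- total_loss(lambda0, tau0, th$alpha, th$psi, W, options)
  structure(
    list(alpha = stats::setNames(th$alpha, fit$groups),
         psi = stats::setNames(th$psi, fit$groups),
         lambda = al$lambda, tau = al$tau,
         loss = as.numeric(lv),
         loss_loading = attr(lv, "loading"),
         loss_threshold = attr(lv, "threshold"),
         weights = W, options = options,
         lambda0 = lambda0, tau0 = tau0,
         group_sizes = fit$group_sizes, groups = fit$groups,
         items = fit$items, link = fit$link, ref_group = ref,
         free_index = free,
         diagnostics = list(start_losses = losses, best_start = best,
                            convergence = vapply(runs, function(r)
                              r$convergence %||% 99L, 0L))),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, digits = 3, ...) {
  cat(sprintf("alignment_result: %d items x %d groups (%s link, %s CLF, %s identification)\n",
              nrow(x$lambda), ncol(x$lambda), x$link, x$options$clf,
              x$options$identification))
  cat(sprintf("total loss F = %.6g (loadings %.6g + thresholds %.6g), best of %d starts\n",
              x$loss, x$loss_loading, x$loss_threshold,
              length(x$diagnostics$start_losses)))
  tab <- data.frame(group = x$groups,
                    mean = round(x$alpha, digits),
                    variance = round(x$psi, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Decompose the total loss by item and by group
#'
#' Item contribution: all loss terms involving that item (they partition
#' the total, so they sum to F).  Group contribution: all terms in pairs
#' involving that group (each term is shared by two groups, so the group
#' column sums to 2F; `group_share` halves it to restore conservation).
#' Loadings and thresholds are reported separately and together.
#'
#' @param result an [align()] result.
#' @return list of class `loss_contributions` with data frames `by_item`
#'   and `by_group` and the `total`.
#' @export
loss_contributions <- function(result) {
  stopifnot(inherits(result, "alignment_result"))
  opt <- result$options
  G <- ncol(result$lambda); P <- nrow(result$lambda)
  W <- result$weights
  lt <- loss_terms(result$lambda, result$tau, W, opt)
  TL <- lt$TL; TT <- lt$TT
  ut <- rep(upper.tri(matrix(0, G, G)), each = P)
  TLu <- TL; TLu[!ut] <- 0
  TTu <- TT; TTu[!ut] <- 0
  item_load <- apply(TLu, 1, sum)
  item_thr <- apply(TTu, 1, sum)
  ## per-group: every term of a pair (g, h) is attributed to both g and h,
  ## so the group totals sum to 2F and group_share (half) restores F
  diag0 <- function(A) { for (g in seq_len(G)) A[, g, g] <- 0; A }
  TLs <- diag0(TL); TTs <- diag0(TT)
  grp_load <- vapply(seq_len(G), function(g) sum(TLs[, g, ]), 0)
  grp_thr <- vapply(seq_len(G), function(g) sum(TTs[, g, ]), 0)
  by_item <- data.frame(item = result$items, loading = item_load,
                        threshold = item_thr,
                        total = item_load + item_thr)
  by_group <- data.frame(group = result$groups, loading = grp_load,
                         threshold = grp_thr,
                         total = grp_load + grp_thr,
                         group_share = (grp_load + grp_thr) / 2)
  structure(list(by_item = by_item, by_group = by_group,
                 total = result$loss),
            class = "loss_contributions")
}

#' @export
print.loss_contributions <- function(x, ...) {
  cat("loss contributions (total F =", format(x$total), ")\n")
  cat("\nby item (most non-invariant first):\n")
  print(x$by_item[order(-x$by_item$total), ], row.names = FALSE)
  cat("\nby group:\n")
  print(x$by_group[order(-x$by_group$total), ], row.names = FALSE)
  invisible(x)
}
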