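## Marginal maximum-likelihood fitting of the configural model: every
## group gets its own loadings and thresholds, with the factor fixed to
## N(0, 1) in each group (the identification the alignment step relaxes).

PARAM_BOUND <- 25  # |lambda|, |tau| box to prevent divergence on
                   # quasi-separated items

## starting values: per-item logistic regression of the item on the
## standardized total score (a cheap proxy for the factor)
start_values_2pl <- function(Y) {
  P <- ncol(Y)
  ts <- rowMeans(Y, na.rm = TRUE)
  z <- as.numeric(scale(ts))
  if (all(!is.finite(z)) || stats::sd(ts, na.rm = TRUE) == 0)
    z <- rep(0, length(ts))
  z[!is.finite(z)] <- 0
  lambda <- numeric(P); tau <- numeric(P)
  for (p in seq_len(P)) {
    ok <- !is.na(Y[, p])
    yv <- Y[ok, p]; zv <- z[ok]
    pbar <- min(max(mean(yv), 0.02), 0.98)
    co <- tryCatch(
      stats::glm.fit(cbind(1, zv), yv,
                     family = stats::binomial())$coefficients,
      error = function(e) c(stats::qlogis(pbar), 1))
    if (any(!is.finite(co))) co <- c(stats::qlogis(pbar), 1)
    lambda[p] <- min(max(co[2], 0.2), 4)
    tau[p] <- min(max(-co[1], -4), 4)
  }
  list(lambda = lambda, tau = tau)
}

## optim wrapper with a shared cache so fn and gr reuse one evaluation
make_objective <- function(fn_grad) {
  cache <- new.env(parent = emptyenv())
  cache$x <- NULL
  eval_at <- function(x) {
    if (is.null(cache$x) || !identical(x, cache$x)) {
      cache$x <- x
      cache$val <- fn_grad(x)
    }
    cache$val
  }
  list(fn = function(x) eval_at(x)$value,
       gr = function(x) eval_at(x)$gradient)
}

#' Fit the two-parameter model to a single group
#'
#' Marginal maximum likelihood for one group's binary responses: the
#' latent factor is integrated out against N(0, 1) by Gauss-Hermite
#' quadrature and the per-item loadings and thresholds maximize the
#' marginal likelihood (quasi-Newton with analytic gradients).  Missing
#' responses drop out of their item's likelihood term.
#'
#' @param block matrix of 0/1/NA responses for one group (rows =
#'   respondents), or a [response_data()] object with a single group
#'   selected via `group`.
#' @param quad [quadrature_spec()].
#' @param link `"logit"` or `"probit"`.
#' @param se compute the observed-information covariance matrix.
#' @param start optional list with `lambda`, `tau` starting values.
#' @return list of class `group_2pl_fit`: `lambda`, `tau`, `loglik`,
#'   `vcov` (order: all loadings then all thresholds), `n`, `items`,
#'   `link`, `convergence`.
#' @export
fit_group_2pl <- function(block, quad = quadrature_spec(),
                          link = c("logit", "probit"), se = TRUE,
                          start = NULL) {
  link <- match.arg(link)
  Y <- as.matrix(block)
  storage.mode(Y) <- "double"
  if (ncol(Y) < 2 || nrow(Y) < 1)
    stop("need at least 2 items and 1 respondent", call. = FALSE)
  items <- colnames(Y) %||% paste0("Y", seq_len(ncol(Y)))
  obs_means <- colMeans(Y, na.rm = TRUE)
  boundary <- which(obs_means %in% c(0, 1))
  if (length(boundary))
    warning("item(s) with all-0 or all-1 observed responses: ",
            paste(items[boundary], collapse = ", "),
            " (estimates at the boundary are unreliable)", call. = FALSE)
  P <- ncol(Y)
  blk <- prep_block(Y)
  rule <- gh_rule(quad$nodes)
  start <- start %||% start_values_2pl(Y)

  obj <- make_objective(function(x) {
    lam <- x[1:P]; tau <- x[(P + 1):(2 * P)]
    gm <- group_marginal(blk, lam, tau, 0, 1, rule, link, grad = TRUE)
    list(value = -gm$loglik,
         gradient = -c(gm$grad$lambda, gm$grad$tau))
  })
  opt <- stats::optim(c(start$lambda, start$tau), obj$fn, obj$gr,
                      method = "L-BFGS-B",
                      lower = rep(-PARAM_BOUND, 2 * P),
                      upper = rep(PARAM_BOUND, 2 * P),
                      control = list(maxit = 500L, factr = 1e4))
  if (opt$convergence != 0)
    stop(sprintf("group fit did not converge (code %d, %d evaluations): %s",
                 opt$convergence, opt$counts[1], opt$message %||% ""),
         call. = FALSE)
  lambda <- opt$par[1:P]; tau <- opt$par[(P + 1):(2 * P)]
  names(lambda) <- names(tau) <- items
  fit <- structure(
    list(lambda = lambda, tau = tau, loglik = -opt$value, vcov = NULL,
         n = nrow(Y), items = items, link = link, quad = quad,
         boundary_items = items[boundary],
         convergence = list(code = opt$convergence, counts = opt$counts)),
    class = "group_2pl_fit")
  fit$.blk <- blk; fit$.rule <- rule
  if (se) fit$vcov <- observed_information_se(fit)$vcov
  fit
}

## per-group marginal loglik at arbitrary parameters and factor
## distribution; used by the constrained fits, the likelihood-equality
## property, and oracles in the tests
group_loglik_at <- function(Y, lambda, tau, alpha = 0, psi = 1,
                            quad = quadrature_spec(), link = "logit") {
  blk <- prep_block(as.matrix(Y))
  rule <- gh_rule(quad$nodes)
  group_marginal(blk, as.numeric(lambda), as.numeric(tau), alpha, psi,
                 rule, link)$loglik
}

#' Construct a configural fit from given estimates
#'
#' Builds the container that [align()] consumes without refitting, e.g.
#' from externally supplied configural estimates or an analytic
#' construction.  `lambda` and `tau` are items-by-groups matrices on the
#' configural scale (factor mean 0, variance 1 in every group).
#'
#' @param lambda,tau numeric P x G matrices.
#' @param group_sizes integer vector of length G.
#' @param link `"logit"` or `"probit"`.
#' @param groups,items optional labels.
#' @param vcov optional list of per-group parameter covariance matrices
#'   (order: loadings then thresholds).
#' @param loglik_by_group optional per-group log-likelihoods.
#' @return an object of class `configural_fit`.
#' @export
configural_fit <- function(lambda, tau, group_sizes,
                           link = c("logit", "probit"), groups = NULL,
                           items = NULL, vcov = NULL,
                           loglik_by_group = NULL) {
  link <- match.arg(link)
  lambda <- as.matrix(lambda); tau <- as.matrix(tau)
  stopifnot(all(dim(lambda) == dim(tau)),
            length(group_sizes) == ncol(lambda))
  G <- ncol(lambda); P <- nrow(lambda)
  groups <- groups %||% colnames(lambda) %||% paste0("g", seq_len(G))
  items <- items %||% rownames(lambda) %||% paste0("Y", seq_len(P))
  dimnames(lambda) <- dimnames(tau) <- list(items, groups)
  loglik_by_group <- loglik_by_group %||% rep(NA_real_, G)
  structure(
    list(lambda = lambda, tau = tau, group_sizes = as.integer(group_sizes),
         groups = groups, items = items, link = link, vcov = vcov,
         loglik_by_group = loglik_by_group,
         loglik = if (all(is.finite(loglik_by_group)))
           sum(loglik_by_group) else NA_real_),
    class = "configural_fit")
}

#' Fit the configural model to multi-group data
#'
#' Independent per-group marginal ML fits with the factor fixed to
#' N(0, 1) in every group; the total log-likelihood is the sum of the
#' per-group log-likelihoods (groups are independent under the
#' configural model).
#'
#' @param data a [response_data()] object.
#' @param quad [quadrature_spec()].
#' @param link `"logit"` or `"probit"`.
#' @param se compute per-group observed-information covariances (needed
#'   for post-alignment standard errors; disable for speed in
#'   simulations).
#' @return an object of class `configural_fit`; additionally carries the
#'   per-group data blocks for downstream likelihood checks.
#' @export
fit_configural <- function(data, quad = quadrature_spec(),
                           link = c("logit", "probit"), se = TRUE) {
  link <- match.arg(link)
  stopifnot(inherits(data, "response_data"))
  G <- length(data$groups); P <- length(data$items)
  lambda <- tau <- matrix(NA_real_, P, G,
                          dimnames = list(data$items, data$groups))
  ll <- numeric(G); vc <- vector("list", G)
  fits <- vector("list", G)
  for (gi in seq_len(G)) {
    g <- data$groups[gi]
    fg <- tryCatch(
      fit_group_2pl(group_block(data, g), quad, link, se = se),
      error = function(e)
        stop(sprintf("group %s: %s", g, conditionMessage(e)), call. = FALSE))
    lambda[, gi] <- fg$lambda; tau[, gi] <- fg$tau
    ll[gi] <- fg$loglik; vc[[gi]] <- fg$vcov
    fits[[gi]] <- fg
  }
  out <- configural_fit(lambda, tau, data$group_sizes, link,
                        groups = data$groups, items = data$items,
                        vcov = if (se) vc else NULL, loglik_by_group = ll)
  out$quad <- quad
  out$group_fits <- fits
  out
}

#' @export
print.configural_fit <- function(x, ...) {
  cat(sprintf("configural_fit: %d items x %d groups (%s link)\n",
              nrow(x$lambda), ncol(x$lambda), x$link))
  if (is.finite(x$loglik))
    cat(sprintf("log-likelihood: %.3f (sum over %d independent groups)\n",
                x$loglik, ncol(x$lambda)))
  cat(sprintf("free measurement parameters: %d\n",
              free_parameter_count("configural", ncol(x$lambda),
                                   nrow(x$lambda))))
  invisible(x)
}
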