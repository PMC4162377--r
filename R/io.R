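## Readers/writers: JSON for machine round-trips (full precision, schema
## version stamped), TSV for human-readable tables (6 significant
## digits).

SCHEMA_VERSION <- "1.0"

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

write_tsv_file <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- JSON representations ------------------------------------------------

as_json_list <- function(x, ...) UseMethod("as_json_list")

#' @export
as_json_list.configural_fit <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "configural_fit",
       link = x$link, groups = x$groups, items = x$items,
       group_sizes = x$group_sizes,
       lambda = unname(apply(x$lambda, 2, as.numeric, simplify = FALSE)),
       tau = unname(apply(x$tau, 2, as.numeric, simplify = FALSE)),
       loglik_by_group = x$loglik_by_group, loglik = x$loglik,
       vcov = if (!is.null(x$vcov))
         lapply(x$vcov, function(V) if (is.null(V)) NULL
                else unname(apply(V, 1, as.numeric, simplify = FALSE))))
}

#' @export
as_json_list.alignment_result <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "alignment_result",
       link = x$link, groups = x$groups, items = x$items,
       group_sizes = x$group_sizes, ref_group = x$ref_group,
       options = unclass(x$options),
       alpha = as.numeric(x$alpha), psi = as.numeric(x$psi),
       lambda = unname(apply(x$lambda, 2, as.numeric, simplify = FALSE)),
       tau = unname(apply(x$tau, 2, as.numeric, simplify = FALSE)),
       lambda0 = unname(apply(x$lambda0, 2, as.numeric, simplify = FALSE)),
       tau0 = unname(apply(x$tau0, 2, as.numeric, simplify = FALSE)),
       loss = x$loss, loss_loading = x$loss_loading,
       loss_threshold = x$loss_threshold,
       diagnostics = x$diagnostics)
}

#' @export
as_json_list.population_spec <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "population_spec",
       link = x$link, groups = x$groups, items = x$items,
       lambda = unname(apply(x$lambda, 2, as.numeric, simplify = FALSE)),
       tau = unname(apply(x$tau, 2, as.numeric, simplify = FALSE)),
       alpha = as.numeric(x$alpha), psi = as.numeric(x$psi),
       ledger = x$ledger, base = x$base, seed = x$seed)
}

#' @export
as_json_list.mc_summary <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "mc_summary",
       n_reps = x$n_reps, n_ok = x$n_ok,
       mean_correlation = x$mean_correlation, reliable = x$reliable,
       bias_alpha = as.numeric(x$bias_alpha),
       rmse_alpha = as.numeric(x$rmse_alpha),
       bias_psi = as.numeric(x$bias_psi),
       coverage_alpha = x$coverage_alpha,
       true_alpha = as.numeric(x$true_alpha),
       failures = x$failures, seed = x$seed)
}

#' @export
as_json_list.constrained_fit <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "constrained_fit",
       level = x$level, link = x$link, groups = x$groups,
       items = x$items,
       lambda = unname(apply(x$lambda, 2, as.numeric, simplify = FALSE)),
       tau = unname(apply(x$tau, 2, as.numeric, simplify = FALSE)),
       alpha = as.numeric(x$alpha), psi = as.numeric(x$psi),
       loglik = x$loglik, n_free = x$n_free)
}

#' @export
tsv_tables.constrained_fit <- function(x, ...) {
  list(distributions = data.frame(group = x$groups,
                                  mean = as.numeric(x$alpha),
                                  variance = as.numeric(x$psi)))
}

#' @export
as_json_list.invariance_flags <- function(x, ...) {
  fam <- function(f) lapply(seq_along(x$items), function(p)
    list(item = x$items[p],
         invariant = as.list(x[[f]]$sets[[p]]$invariant),
         flagged = as.list(x[[f]]$sets[[p]]$flagged)))
  list(schema_version = SCHEMA_VERSION, type = "invariance_flags",
       alpha_level = x$alpha_level, groups = x$groups, items = x$items,
       threshold = fam("threshold"), loading = fam("loading"))
}

#' @export
as_json_list.noninvariance_summary <- function(x, ...) {
  c(list(schema_version = SCHEMA_VERSION, type = "noninvariance_summary"),
    unclass(x))
}

#' @export
as_json_list.mean_ranking <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "mean_ranking",
       alpha_level = attr(x, "alpha_level"),
       ranking = as.data.frame(x))
}

#' @export
as_json_list.lrt <- function(x, ...) {
  list(schema_version = SCHEMA_VERSION, type = "likelihood_ratio_test",
       general = unname(x$models["general"]),
       restricted = unname(x$models["restricted"]),
       statistic = x$statistic, df = x$df, p_value = x$p.value)
}

cols_to_matrix <- function(cols, items, groups) {
  m <- do.call(cbind, lapply(cols, unlist))
  dimnames(m) <- list(items, groups)
  m
}

#' Read a configural fit from JSON
#'
#' Reads configural estimates written by [write_results()] (or supplied
#' externally, e.g. an analytic construction) so the alignment engine
#' can run without refitting.
#'
#' @param path JSON file path.
#' @return a `configural_fit`.
#' @export
read_configural_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "configural_fit"))
    stop("not a configural_fit JSON: ", path, call. = FALSE)
  items <- unlist(j$items); groups <- unlist(j$groups)
  fit <- configural_fit(cols_to_matrix(j$lambda, items, groups),
                        cols_to_matrix(j$tau, items, groups),
                        unlist(j$group_sizes), j$link,
                        groups = groups, items = items,
                        loglik_by_group = unlist(j$loglik_by_group))
  if (!is.null(j$vcov))
    fit$vcov <- lapply(j$vcov, function(rows)
      if (is.null(rows)) NULL else do.call(rbind, lapply(rows, unlist)))
  fit
}

#' Read an alignment result from JSON
#'
#' @param path JSON file path written by [write_results()].
#' @return an `alignment_result` (losslessly reconstructed).
#' @export
read_alignment_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "alignment_result"))
    stop("not an alignment_result JSON: ", path, call. = FALSE)
  items <- unlist(j$items); groups <- unlist(j$groups)
  opt <- j$options
  options <- alignment_options(
    epsilon = opt$epsilon, clf = opt$clf, weights = opt$weights,
    identification = opt$identification, ref_group = opt$ref_group,
    n_starts = opt$n_starts, sd_alpha = opt$sd_alpha,
    sd_logpsi = opt$sd_logpsi, tol = opt$tol, seed = opt$seed)
  structure(
    list(alpha = stats::setNames(unlist(j$alpha), groups),
         psi = stats::setNames(unlist(j$psi), groups),
         lambda = cols_to_matrix(j$lambda, items, groups),
         tau = cols_to_matrix(j$tau, items, groups),
         loss = j$loss, loss_loading = j$loss_loading,
         loss_threshold = j$loss_threshold,
         weights = pair_weights(unlist(j$group_sizes), options$weights),
         options = options,
         lambda0 = cols_to_matrix(j$lambda0, items, groups),
         tau0 = cols_to_matrix(j$tau0, items, groups),
         group_sizes = unlist(j$group_sizes), groups = groups,
         items = items, link = j$link, ref_group = j$ref_group,
         free_index = setdiff(seq_along(groups), j$ref_group),
         diagnostics = list(
           start_losses = unlist(j$diagnostics$start_losses),
           best_start = j$diagnostics$best_start,
           convergence = unlist(j$diagnostics$convergence))),
    class = "alignment_result")
}

#' Read a population spec from JSON
#'
#' @param path JSON file path written by [write_results()].
#' @return a `population_spec`.
#' @export
read_population_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$type, "population_spec"))
    stop("not a population_spec JSON: ", path, call. = FALSE)
  items <- unlist(j$items); groups <- unlist(j$groups)
  led <- if (length(j$ledger))
    do.call(rbind, lapply(j$ledger, as.data.frame))
  else data.frame(family = character(), item = character(),
                  group = character(), delta = numeric())
  structure(list(G = length(groups), P = length(items),
                 lambda = cols_to_matrix(j$lambda, items, groups),
                 tau = cols_to_matrix(j$tau, items, groups),
                 alpha = stats::setNames(unlist(j$alpha), groups),
                 psi = stats::setNames(unlist(j$psi), groups),
                 link = j$link, ledger = led,
                 base = lapply(j$base, unlist),
                 seed = j$seed %||% NA_integer_,
                 groups = groups, items = items),
            class = "population_spec")
}

## ---- TSV tables ----------------------------------------------------------

tsv_tables <- function(x, ...) UseMethod("tsv_tables")

#' @export
tsv_tables.configural_fit <- function(x, ...) {
  G <- ncol(x$lambda)
  list(parameters = data.frame(
    item = rep(x$items, G), group = rep(x$groups, each = nrow(x$lambda)),
    loading = as.numeric(x$lambda), threshold = as.numeric(x$tau)))
}

#' @export
tsv_tables.alignment_result <- function(x, ...) {
  G <- ncol(x$lambda)
  list(
    distributions = data.frame(group = x$groups,
                               mean = as.numeric(x$alpha),
                               variance = as.numeric(x$psi)),
    aligned_parameters = data.frame(
      item = rep(x$items, G), group = rep(x$groups, each = nrow(x$lambda)),
      loading = as.numeric(x$lambda), threshold = as.numeric(x$tau)))
}

#' @export
tsv_tables.mean_ranking <- function(x, ...) {
  list(ranking = as.data.frame(x))
}

#' @export
tsv_tables.mc_summary <- function(x, ...) {
  list(mc_groups = data.frame(group = names(x$true_alpha),
                              true_mean = as.numeric(x$true_alpha),
                              bias = as.numeric(x$bias_alpha),
                              rmse = as.numeric(x$rmse_alpha)))
}

#' @export
tsv_tables.default <- function(x, ...) list()

#' Write result objects to an output directory
#'
#' Each object is written as JSON (full precision, schema version
#' stamped) and, where a tabular form exists, as TSV with 6 significant
#' digits.  Files are named `<name>.json` / `<name>_<table>.tsv`.
#'
#' @param objects named list of package result objects.
#' @param outdir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_results <- function(objects, outdir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    x <- objects[[nm]]
    jl <- tryCatch(as_json_list(x), error = function(e) NULL)
    if (!is.null(jl)) {
      p <- file.path(outdir, paste0(nm, ".json"))
      tryCatch(write_json_file(jl, p),
               error = function(e) stop("failed writing ", p, ": ",
                                        conditionMessage(e), call. = FALSE))
      paths <- c(paths, p)
    }
    for (tn in names(tsv_tables(x))) {
      p <- file.path(outdir, paste0(nm, "_", tn, ".tsv"))
      tryCatch(write_tsv_file(tsv_tables(x)[[tn]], p),
               error = function(e) stop("failed writing ", p, ": ",
                                        conditionMessage(e), call. = FALSE))
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
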