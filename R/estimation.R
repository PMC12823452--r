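#' Estimator configuration
#'
#' Collects every setting of the correlation + EBIC-glasso pipeline so that
#' permutation, bootstrap and imputation re-runs use one identical
#' estimator.
#'
#' @param method,missing Passed to [weighted_correlation()].
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio Regularization path: `n_lambda`
#'   log-spaced penalties from `lambda_max` (largest absolute off-diagonal
#'   correlation, where the network is empty) down to
#'   `lambda_min_ratio * lambda_max`.
#' @param gap_tol Duality-gap convergence tolerance of the glasso solver.
#' @param edge_tol Threshold separating numerical zeros from edges.
#' @return An `estimator_config` list.
#' @export
estimator_config <- function(method = c("pearson", "spearman"),
                             missing = c("pairwise", "listwise"),
                             gamma = 0.5, n_lambda = 100,
                             lambda_min_ratio = 0.01,
                             gap_tol = 1e-6, edge_tol = 1e-10) {
  stopifnot(gamma >= 0, n_lambda >= 1, lambda_min_ratio > 0,
            lambda_min_ratio <= 1)
  structure(
    list(method = match.arg(method), missing = match.arg(missing),
         gamma = gamma, n_lambda = n_lambda,
         lambda_min_ratio = lambda_min_ratio,
         gap_tol = gap_tol, edge_tol = edge_tol),
    class = "estimator_config"
  )
}

corr_input <- function(corr) {
  if (inherits(corr, "weighted_corr"))
    list(S = corr$matrix, n = corr$n, nodes = corr$nodes)
  else {
    S <- as.matrix(corr)
    nodes <- colnames(S)
    if (is.null(nodes)) nodes <- paste0("V", seq_len(ncol(S)))
    list(S = S, n = NULL, nodes = nodes)
  }
}

#' Graphical lasso at a single penalty
#'
#' Solves `max log det K - tr(SK) - lambda * sum_{i != j} |k_ij|` (diagonal
#' unpenalized) by blockwise coordinate descent, monitored by the duality
#' gap, and reports the fit together with the implied regularized
#' partial-correlation matrix and its EBIC.
#'
#' @param corr A [weighted_correlation()] result or a plain positive-definite
#'   correlation matrix.
#' @param lambda Penalty, `>= 0`.
#' @param n Case count for the likelihood (taken from `corr` when available).
#' @param gamma EBIC hyperparameter.
#' @param gap_tol,edge_tol,maxit Solver controls.
#' @return A `ggm_fit`: `lambda`, `precision`, `partial` (zero diagonal),
#'   `n_edges`, `loglik`, `ebic`, `gamma`, `n`, `p`, `gap`.
#' @export
glasso_fit <- function(corr, lambda, n = NULL, gamma = 0.5,
                       gap_tol = 1e-6, edge_tol = 1e-10, maxit = 200) {
  ci <- corr_input(corr)
  if (is.null(n)) n <- ci$n
  if (is.null(n)) abort("`n` is required when `corr` is a plain matrix")
  if (lambda < 0) abort("`lambda` must be non-negative")
  fit <- glasso_single_cpp(ci$S, lambda, maxit = maxit, gap_tol = gap_tol)
  if (!fit$converged)
    abort(sprintf(
      "graphical lasso did not converge at lambda = %.6g (duality gap %.3g)",
      lambda, fit$gap))
  P <- fit$partial
  dimnames(P) <- dimnames(fit$precision) <- list(ci$nodes, ci$nodes)
  E <- sum(abs(P[upper.tri(P)]) > edge_tol)
  ll <- gauss_loglik_r(ci$S, fit$precision, n)
  structure(
    list(lambda = lambda, precision = fit$precision, partial = P,
         n_edges = E, loglik = ll,
         ebic = ebic_value(ll, E, n, gamma, ncol(P)),
         gamma = gamma, n = n, p = ncol(P), gap = fit$gap, S = ci$S),
    class = "ggm_fit"
  )
}

gauss_loglik_r <- function(S, K, n) {
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) abort("precision matrix is not positive definite")
  0.5 * n * (as.numeric(ld$modulus) - sum(S * K))
}

ebic_value <- function(loglik, E, n, gamma, p)
  -2 * loglik + E * log(n) + 4 * E * gamma * log(p)

#' Extended Bayesian information criterion of a fitted GGM
#'
#' `EBIC = -2 loglik + E log(n) + 4 E gamma log(p)` with
#' `loglik = (n/2)(log det K - tr(SK))` (data-independent constants dropped
#' consistently across a path); at `gamma = 0` this is the ordinary BIC
#' penalty `E log n`.
#'
#' @param fit A [glasso_fit()] result.
#' @param n Case count (default: the fit's).
#' @param gamma Hyperparameter `>= 0` (default: the fit's).
#' @return The EBIC value.
#' @export
ebic <- function(fit, n = fit$n, gamma = fit$gamma) {
  stopifnot(inherits(fit, "ggm_fit"))
  if (n < 2) abort("`n` must be at least 2")
  if (gamma < 0) abort("`gamma` must be non-negative")
  ll <- gauss_loglik_r(fit$S, fit$precision, n)
  ebic_value(ll, fit$n_edges, n, gamma, fit$p)
}

lambda_grid <- function(S, n_lambda, lambda_min_ratio) {
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax <= 0) return(0)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso along a descending log-spaced penalty path
#' (warm-started) and returns the network minimizing the EBIC at the given
#' `gamma` (default 0.5); ties go to the larger penalty, i.e. the sparser
#' model.
#'
#' @inheritParams glasso_fit
#' @param n_lambda,lambda_min_ratio Path settings (see [estimator_config()]).
#' @param communities Optional community map attached to the model.
#' @return A `network_model`: `weights` (the selected partial-correlation
#'   matrix), `node_names`, `communities`, `path` (per-lambda tibble), and
#'   provenance (`lambda`, `gamma`, `n`, `ebic`, `n_edges`).
#' @export
#' @examples
#' S <- diag(4)
#' net <- ebic_glasso(S, n = 100)
#' net$n_edges
ebic_glasso <- function(corr, n = NULL, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01, communities = NULL,
                        gap_tol = 1e-6, edge_tol = 1e-10) {
  ci <- corr_input(corr)
  if (is.null(n)) n <- ci$n
  if (is.null(n)) abort("`n` is required when `corr` is a plain matrix")
  lambdas <- lambda_grid(ci$S, n_lambda, lambda_min_ratio)
  res <- glasso_path_cpp(ci$S, lambdas, n, gamma,
                         gap_tol = gap_tol, edge_tol = edge_tol)
  W <- res$best_partial
  W[abs(W) <= edge_tol] <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(ci$nodes, ci$nodes)
  new_network_model(
    weights = W, communities = communities,
    provenance = list(
      lambda = res$best_lambda, gamma = gamma, n = n,
      ebic = res$best_ebic, n_lambda = n_lambda,
      lambda_min_ratio = lambda_min_ratio,
      correlation = if (inherits(corr, "weighted_corr"))
        list(method = corr$method, missing = corr$missing,
             repaired = corr$repaired) else NULL),
    path = tibble::tibble(
      lambda = as.numeric(res$lambda), n_edges = as.integer(res$n_edges),
      loglik = as.numeric(res$loglik), ebic = as.numeric(res$ebic),
      converged = as.logical(res$converged)),
    precision = res$best_precision
  )
}

new_network_model <- function(weights, communities, provenance,
                              path = NULL, precision = NULL) {
  structure(
    list(weights = weights, node_names = colnames(weights),
         communities = communities,
         n_edges = sum(abs(weights[upper.tri(weights)]) > 0),
         lambda = provenance$lambda, gamma = provenance$gamma,
         n = provenance$n, ebic = provenance$ebic,
         provenance = provenance, path = path, precision = precision),
    class = "network_model"
  )
}

#' Estimate a regularized partial-correlation network from survey data
#'
#' One call from respondent-level data to the selected network: weighted
#' available-case correlation, positive-definiteness repair if needed, then
#' EBIC-glasso selection.
#'
#' @param data Survey tibble.
#' @param communities Community map (node, community).
#' @param weights Weight column name (or `NULL`).
#' @param config An [estimator_config()].
#' @return A `network_model` (see [ebic_glasso()]).
#' @export
estimate_network <- function(data, communities = cfm_communities(),
                             weights = "weight",
                             config = estimator_config()) {
  check_schema(data, communities)
  wc <- weighted_correlation(data, nodes = communities$node,
                             weights = weights, method = config$method,
                             missing = config$missing)
  ebic_glasso(wc, gamma = config$gamma, n_lambda = config$n_lambda,
              lambda_min_ratio = config$lambda_min_ratio,
              communities = communities, gap_tol = config$gap_tol,
              edge_tol = config$edge_tol)
}

#' @export
print.network_model <- function(x, ...) {
  cat("Regularized partial-correlation network\n")
  cat(sprintf("  %d nodes, %d edges; lambda = %.4g (EBIC gamma = %.2g, n = %s)\n",
              length(x$node_names), x$n_edges, x$lambda, x$gamma,
              format(x$n)))
  invisible(x)
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("GGM fit: lambda = %.4g, %d edges, EBIC = %.2f (gamma = %.2g)\n",
              x$lambda, x$n_edges, x$ebic, x$gamma))
  invisible(x)
}

#' Tidiers for fitted networks
#'
#' `tidy()` returns the long-form edge list (zero edges omitted);
#' `glance()` a one-row model summary.
#'
#' @param x A `network_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.network_model <- function(x, ...) {
  W <- x$weights
  idx <- which(upper.tri(W) & abs(W) > 0, arr.ind = TRUE)
  tibble::tibble(
    node_a = x$node_names[idx[, 1]],
    node_b = x$node_names[idx[, 2]],
    weight = W[idx]
  ) |> dplyr::arrange(.data$node_a, .data$node_b)
}

#' @rdname tidy.network_model
#' @export
glance.network_model <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$node_names), n_edges = x$n_edges,
    lambda = x$lambda, gamma = x$gamma, n = x$n, ebic = x$ebic,
    global_strength = global_strength(x)
  )
}

#' Serialize a network model
#'
#' Writes the weights matrix as a square CSV, the non-zero edges as a
#' long-form CSV, and the provenance as JSON.
#'
#' @param net A `network_model`.
#' @param basename Path prefix; writes `<basename>_matrix.csv`,
#'   `<basename>_edges.csv`, `<basename>_provenance.json`.
#' @export
write_network <- function(net, basename) {
  stopifnot(inherits(net, "network_model"))
  write.csv(net$weights, paste0(basename, "_matrix.csv"), row.names = TRUE)
  write.csv(tidy(net), paste0(basename, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(net$provenance, paste0(basename, "_provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(basename)
}
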