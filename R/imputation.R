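#' Chained-equations multiple imputation with predictive mean matching
#'
#' The sensitivity path for missing item responses. Missing cells are
#' initialized by weighted random draws from each node's observed marginal;
#' then, cycling nodes in increasing-missingness order, each node is imputed
#' by predictive mean matching (donor pool `k = 5`) regressed on all other
#' nodes plus the sampling weight and group columns. Regression coefficients
#' for the missing-cell predictions are perturbed by a draw from their
#' sampling distribution, so the `m` chains are proper, independent
#' imputations. Because donors are observed responses, imputed codes are
#' always valid categories, and observed cells are never altered.
#'
#' @param data Survey tibble.
#' @param communities Community map (its nodes are the imputed columns).
#' @param weights Weight column used as a predictor (or `NULL`).
#' @param group_vars Categorical columns used as predictors.
#' @param m Number of imputations (default 10).
#' @param n_iterations Chained-equation cycles per imputation (default 10).
#' @param k Donor-pool size for predictive mean matching.
#' @param seed Integer seed.
#' @return An `imputed_set`: `tables` (list of `m` completed tibbles), `m`,
#'   `n_iterations`, `order` (imputation order), `seed`. `tidy()` stacks the
#'   completed tables with an `.imp` index column.
#' @export
impute_chained <- function(data, communities = cfm_communities(),
                           weights = "weight",
                           group_vars = intersect(c("gender", "age_group"),
                                                  names(data)),
                           m = 10, n_iterations = 10, k = 5, seed = NULL) {
  check_schema(data, communities)
  nodes <- communities$node
  X <- as.matrix(data[nodes]); storage.mode(X) <- "double"
  n <- nrow(X)
  n_miss <- colSums(is.na(X))
  if (any(n_miss == n))
    abort(paste0("node(s) entirely missing: ",
                 paste(nodes[n_miss == n], collapse = ", ")))
  if (any(n_miss > 0.5 * n))
    abort(paste0("node(s) with more than 50% missingness: ",
                 paste(nodes[n_miss > 0.5 * n], collapse = ", ")))
  w <- if (is.null(weights)) rep(1, n) else as.numeric(data[[weights]])

  # fixed (always observed) predictors: weight + one-hot group columns
  fixed <- cbind(weight = w)
  for (v in group_vars) {
    f <- factor(data[[v]])
    if (nlevels(f) > 1)
      fixed <- cbind(fixed, stats::model.matrix(~ f)[, -1, drop = FALSE])
  }
  order_vars <- order(n_miss)  # increasing missingness
  impute_vars <- order_vars[n_miss[order_vars] > 0]

  local_seed(seed)
  tables <- vector("list", m)
  for (chain in seq_len(m)) {
    Xc <- X
    # initialize by weighted draws from observed marginals
    for (j in impute_vars) {
      mis <- is.na(X[, j]); obs <- which(!mis)
      Xc[mis, j] <- X[sample(obs, sum(mis), replace = TRUE,
                             prob = w[obs] / sum(w[obs])), j]
    }
    for (it in seq_len(n_iterations)) {
      for (j in impute_vars) {
        mis <- is.na(X[, j])
        pred <- cbind(1, Xc[, -j, drop = FALSE], fixed)
        Xc[mis, j] <- pmm_draw(y_obs = X[!mis, j],
                               X_obs = pred[!mis, , drop = FALSE],
                               X_mis = pred[mis, , drop = FALSE], k = k)
      }
    }
    out <- data
    out[nodes] <- tibble::as_tibble(as.data.frame(Xc))
    tables[[chain]] <- out
  }
  structure(
    list(tables = tables, m = m, n_iterations = n_iterations,
         order = nodes[impute_vars], k = k, seed = seed),
    class = "imputed_set"
  )
}

# predictive mean matching: ridge-stabilized least squares on observed rows,
# parameter draw for the missing-row predictions, k-nearest-donor sampling
pmm_draw <- function(y_obs, X_obs, X_mis, k = 5) {
  if (!nrow(X_mis)) return(numeric(0))
  XtX <- crossprod(X_obs)
  ridge <- diag(1e-8 * max(diag(XtX), 1), ncol(XtX))
  ch <- chol(XtX + ridge)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(X_obs, y_obs)))
  resid <- y_obs - X_obs %*% beta
  df <- max(nrow(X_obs) - ncol(X_obs), 1)
  sigma <- sqrt(sum(resid^2) / df)
  # beta* ~ N(beta, sigma^2 (X'X)^-1): perturb via the Cholesky factor
  z <- rnorm(ncol(X_obs))
  beta_star <- beta + sigma * backsolve(ch, z)
  yhat_obs <- drop(X_obs %*% beta)
  yhat_mis <- drop(X_mis %*% beta_star)
  # k-nearest-donor search against predictions sorted once
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  yo <- y_obs[ord]
  n_obs <- length(ys)
  pos <- findInterval(yhat_mis, ys)
  vapply(seq_along(yhat_mis), function(i) {
    win <- max(1L, pos[i] - k):min(n_obs, pos[i] + k)
    d <- abs(ys[win] - yhat_mis[i])
    pool <- win[order(d)[seq_len(min(k, length(win)))]]
    yo[sample(pool, 1L)]
  }, numeric(1))
}

#' @export
print.imputed_set <- function(x, ...) {
  cat(sprintf("Chained-equation imputation: m = %d, %d cycles, PMM donors k = %d\n",
              x$m, x$n_iterations, x$k))
  invisible(x)
}

#' @rdname impute_chained
#' @param x An `imputed_set`.
#' @param ... Unused.
#' @export
tidy.imputed_set <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$tables, ~ dplyr::mutate(.x, .imp = .y)))
}

#' Pooled network across multiply imputed datasets
#'
#' Estimates a weighted correlation matrix on each completed table, averages
#' the `m` matrices element-wise, repairs positive definiteness if needed,
#' and runs the EBIC-glasso once on the pooled matrix. (Averaging on the
#' correlation scale rather than averaging `m` regularized networks is a
#' declared convention: Rubin's rules do not apply to penalized edge sets.)
#'
#' @param imputed An [impute_chained()] result.
#' @param communities Community map.
#' @param weights Weight column name.
#' @param config [estimator_config()].
#' @return A `network_model` whose provenance records `m`.
#' @export
pooled_network <- function(imputed, communities = cfm_communities(),
                           weights = "weight",
                           config = estimator_config()) {
  stopifnot(inherits(imputed, "imputed_set"))
  wcs <- purrr::map(imputed$tables, function(tab)
    weighted_correlation(tab, nodes = communities$node, weights = weights,
                         method = config$method, missing = config$missing,
                         repair = FALSE))
  S <- Reduce(`+`, purrr::map(wcs, "matrix")) / imputed$m
  S <- nearest_pd_repair(S)$matrix
  n <- wcs[[1]]$n
  net <- ebic_glasso(S, n = n, gamma = config$gamma,
                     n_lambda = config$n_lambda,
                     lambda_min_ratio = config$lambda_min_ratio,
                     communities = communities,
                     gap_tol = config$gap_tol, edge_tol = config$edge_tol)
  net$provenance$m_imputations <- imputed$m
  net
}
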