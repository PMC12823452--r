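#' Non-parametric bootstrap of edges and centralities
#'
#' Resamples respondents with replacement (weights travel with their
#' respondents, unrenormalized), reruns the full estimation pipeline
#' (weighted correlation, PD repair, EBIC-glasso, centralities) on each
#' resample, and returns percentile 95% confidence intervals for every edge
#' weight, every node's expected influence, and every bridge node's bridge
#' expected influence. Resamples on which the estimator fails (e.g. a
#' degenerate correlation) are counted and excluded from the quantiles; more
#' than 5% failures aborts, signalling an unstable configuration.
#'
#' @inheritParams network_compare
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @return An `edge_bootstrap` object; `tidy()` gives one row per quantity
#'   (`entity`, `type` in edge/ei/bei, `estimate`, `boot_mean`, `lower`,
#'   `upper`).
#' @export
bootstrap_network <- function(data, communities = cfm_communities(),
                              weights = "weight",
                              config = estimator_config(),
                              n_boot = 5000, seed = NULL,
                              bridge = c("wellbeing", "disability")) {
  check_schema(data, communities)
  nodes <- communities$node
  X <- as.matrix(data[nodes]); storage.mode(X) <- "double"
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(data[[weights]])
  comm <- community_lookup(communities)[nodes]
  bridge_idx <- which(comm %in% bridge)
  n <- nrow(X)
  if (n_boot < 1) abort("`n_boot` must be at least 1")

  stats_of <- function(idx) {
    fit <- estimate_W(X[idx, , drop = FALSE], w[idx], config)
    W <- fit$W
    c(W[upper.tri(W)], rowSums(W),
      bei_vector(W, comm, bridge[1], bridge[2])[bridge_idx])
  }
  labels <- c(edge_labels(nodes), nodes, nodes[bridge_idx])
  types <- c(rep("edge", length(nodes) * (length(nodes) - 1) / 2),
             rep("ei", length(nodes)), rep("bei", length(bridge_idx)))

  local_seed(seed)
  point <- stats_of(seq_len(n))
  draws <- matrix(NA_real_, n_boot, length(point))
  failed <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- tryCatch(stats_of(idx), error = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else draws[b, ] <- res
  }
  if (failed > 0.05 * n_boot)
    abort(sprintf(
      "%d of %d bootstrap resamples failed (> 5%%); estimator unstable on these data",
      failed, n_boot))
  ok <- !is.na(draws[, 1])
  lo <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.025)
  hi <- apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.975)
  structure(
    list(table = tibble::tibble(
           entity = labels, type = types, estimate = point,
           boot_mean = colMeans(draws[ok, , drop = FALSE]),
           lower = unname(lo), upper = unname(hi)),
         n_boot = n_boot, n_failed = failed, seed = seed,
         draws = draws, bridge = bridge),
    class = "edge_bootstrap"
  )
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf("Non-parametric bootstrap: %d resamples (%d failed)\n",
              x$n_boot, x$n_failed))
  print(head(x$table, 10))
  invisible(x)
}

#' @rdname bootstrap_network
#' @export
tidy.edge_bootstrap <- function(x, ...) x$table

#' @rdname bootstrap_network
#' @export
glance.edge_bootstrap <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n_failed = x$n_failed)
}

#' Case-dropping bootstrap and the correlation-stability coefficient
#'
#' For each drop proportion `q` in `drop_grid`, repeatedly subsamples
#' `(1 - q) * n` respondents without replacement, re-estimates the network,
#' and records the Pearson correlation between the subsample centrality
#' vector and the full-sample one. The correlation-stability (CS)
#' coefficient is the largest `q` at which the correlation stays at or above
#' 0.7 with empirical probability at least 0.95 (0 if no grid point
#' qualifies). Benchmarks: 0.25 adequate, 0.5 good stability.
#'
#' @inheritParams bootstrap_network
#' @param centrality `"bei"` (default, over the bridge nodes) or `"ei"`
#'   (over all nodes).
#' @param drop_grid Grid of drop proportions in (0, 0.75].
#' @param n_boot Total resample budget, split evenly across the grid
#'   (default 5000).
#' @param cor_threshold,prob_threshold CS definition constants (0.7, 0.95).
#' @return A `stability_result`; `tidy()` gives raw correlation draws,
#'   `glance()` the CS coefficient.
#' @export
case_dropping_stability <- function(data, communities = cfm_communities(),
                                    weights = "weight",
                                    config = estimator_config(),
                                    centrality = c("bei", "ei"),
                                    drop_grid = seq(0.05, 0.75, by = 0.1),
                                    n_boot = 5000, seed = NULL,
                                    bridge = c("wellbeing", "disability"),
                                    cor_threshold = 0.7,
                                    prob_threshold = 0.95) {
  centrality <- match.arg(centrality)
  check_schema(data, communities)
  if (max(drop_grid) > 0.75 || min(drop_grid) <= 0)
    abort("`drop_grid` must lie in (0, 0.75]")
  nodes <- communities$node
  X <- as.matrix(data[nodes]); storage.mode(X) <- "double"
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(data[[weights]])
  comm <- community_lookup(communities)[nodes]
  bridge_idx <- which(comm %in% bridge)
  n <- nrow(X)
  p <- length(nodes)

  cent_of <- function(idx) {
    W <- estimate_W(X[idx, , drop = FALSE], w[idx], config)$W
    if (centrality == "ei") rowSums(W)
    else bei_vector(W, comm, bridge[1], bridge[2])[bridge_idx]
  }

  local_seed(seed)
  full <- cent_of(seq_len(n))
  per_q <- max(1L, floor(n_boot / length(drop_grid)))
  draws <- list()
  skipped <- character(0)
  for (q in drop_grid) {
    n_sub <- round((1 - q) * n)
    if (n_sub < p) {
      skipped <- c(skipped, sprintf(
        "q = %.2f skipped: subsample size %d below node count %d", q, n_sub, p))
      next
    }
    cors <- numeric(per_q)
    for (b in seq_len(per_q)) {
      idx <- sample.int(n, n_sub)
      sub <- tryCatch(cent_of(idx), error = function(e) NULL)
      cors[b] <- if (is.null(sub) || sd(sub) == 0 || sd(full) == 0)
        NA_real_ else cor(full, sub)
    }
    draws[[as.character(q)]] <- cors
  }
  if (length(skipped)) for (msg in skipped) warn(msg)
  draw_tbl <- dplyr::bind_rows(purrr::imap(
    draws, ~ tibble::tibble(drop_proportion = as.numeric(.y), correlation = .x)))
  cs <- cs_from_draws(draw_tbl, cor_threshold, prob_threshold)
  structure(
    list(draws = draw_tbl, cs_coefficient = cs,
         centrality = centrality, drop_grid = drop_grid,
         n_boot_per_proportion = per_q, seed = seed,
         cor_threshold = cor_threshold, prob_threshold = prob_threshold,
         benchmarks = c(adequate = 0.25, good = 0.5),
         skipped = skipped, full_centrality = full),
    class = "stability_result"
  )
}

#' Recompute the CS coefficient from raw stability draws
#'
#' The audit path: given the stored per-proportion correlation draws, find
#' the largest drop proportion whose correlations reach `cor_threshold` with
#' probability at least `prob_threshold` (`NA` draws count as failures).
#'
#' @param draw_tbl Tibble with `drop_proportion` and `correlation`.
#' @param cor_threshold,prob_threshold CS definition constants.
#' @return The CS coefficient (0 if no proportion qualifies).
#' @export
cs_from_draws <- function(draw_tbl, cor_threshold = 0.7,
                          prob_threshold = 0.95) {
  ok <- draw_tbl |>
    dplyr::group_by(.data$drop_proportion) |>
    dplyr::summarise(
      prob = mean(!is.na(.data$correlation) &
                    .data$correlation >= cor_threshold)) |>
    dplyr::filter(.data$prob >= prob_threshold)
  if (!nrow(ok)) 0 else max(ok$drop_proportion)
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Case-dropping stability (%s): CS = %.2f (adequate >= %.2f, good >= %.2f)\n",
    x$centrality, x$cs_coefficient, x$benchmarks["adequate"],
    x$benchmarks["good"]))
  invisible(x)
}

#' @rdname case_dropping_stability
#' @export
tidy.stability_result <- function(x, ...) x$draws

#' @rdname case_dropping_stability
#' @export
glance.stability_result <- function(x, ...) {
  tibble::tibble(cs_coefficient = x$cs_coefficient,
                 centrality = x$centrality,
                 n_boot_per_proportion = x$n_boot_per_proportion)
}

#' Serialize robustness results
#'
#' @param x An `edge_bootstrap` or `stability_result`.
#' @param path Output path (CSV for the bootstrap table, JSON for stability
#'   with raw draws retained for audit).
#' @export
write_bootstrap <- function(x, path) {
  stopifnot(inherits(x, "edge_bootstrap"))
  write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bootstrap
#' @export
write_stability <- function(x, path) {
  stopifnot(inherits(x, "stability_result"))
  jsonlite::write_json(
    list(cs_coefficient = x$cs_coefficient, centrality = x$centrality,
         drop_grid = x$drop_grid,
         n_boot_per_proportion = x$n_boot_per_proportion,
         cor_threshold = x$cor_threshold, prob_threshold = x$prob_threshold,
         benchmarks = as.list(x$benchmarks),
         draws = x$draws),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
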