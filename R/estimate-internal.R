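# Lean matrix-level estimation path shared by the permutation, bootstrap and
# stability engines: no tibble construction, positive definiteness checked by
# Cholesky and repaired only when necessary.

ensure_pd_matrix <- function(R, eig_floor = 1e-8) {
  ok <- tryCatch({chol(R); TRUE}, error = function(e) FALSE)
  if (ok) return(R)
  nearest_pd_repair(R, eig_floor = eig_floor)$matrix
}

# X: numeric matrix of node columns; w: weights.
# Returns the selected partial-correlation (weights) matrix plus n.
estimate_W <- function(X, w, config) {
  res <- wcorr_matrix(X, w, method = config$method, missing = config$missing)
  S <- ensure_pd_matrix(res$R)
  lambdas <- lambda_grid(S, config$n_lambda, config$lambda_min_ratio)
  fit <- glasso_path_cpp(S, lambdas, res$n, config$gamma,
                         gap_tol = config$gap_tol,
                         edge_tol = config$edge_tol)
  W <- fit$best_partial
  W[abs(W) <= config$edge_tol] <- 0
  dimnames(W) <- dimnames(S)
  list(W = W, n = res$n, lambda = fit$best_lambda)
}

# upper-triangle edge labels in fixed order
edge_labels <- function(nodes) {
  idx <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
  paste0(nodes[idx[, 1]], "--", nodes[idx[, 2]])
}
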