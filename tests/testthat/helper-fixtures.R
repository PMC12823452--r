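# Shared fixtures: everything is generated in code at test time.

# fast estimator settings for simulation-heavy tests
tiny_config <- function(...) estimator_config(n_lambda = 20, ...)

# default CFM-like survey at reduced size
small_survey <- function(n = 300, missing_rate = 0, seed = 1,
                         use_default_edits = TRUE) {
  simulate_survey(
    cfm_spec(n_per_group = n, missing_rate = missing_rate,
             use_default_edits = use_default_edits),
    seed = seed)
}

# random positive-definite correlation matrix
random_pd_corr <- function(p, jitter = 0) {
  A <- matrix(rnorm(p * p), p)
  S <- cov2cor(crossprod(A) + (p + jitter) * diag(p))
  colnames(S) <- rownames(S) <- paste0("v", seq_len(p))
  S
}

# independent dense-inversion oracle for partial correlations
partial_oracle <- function(S) {
  K <- solve(S)
  P <- -K / sqrt(outer(diag(K), diag(K)))
  diag(P) <- 0
  P
}

# build a network_model directly from an edge list (toy networks)
make_net <- function(nodes, community, edges = NULL) {
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (!is.null(edges))
    for (i in seq_len(nrow(edges))) {
      W[edges$from[i], edges$to[i]] <- edges$weight[i]
      W[edges$to[i], edges$from[i]] <- edges$weight[i]
    }
  bridgenet:::new_network_model(
    weights = W,
    communities = tibble::tibble(node = nodes, community = community),
    provenance = list(lambda = 0, gamma = 0.5, n = NA_integer_, ebic = NA_real_))
}

# random sparse toy network over the three communities
random_toy_net <- function(p_well = 2, p_dis = 4, p_conf = 2,
                           density = 0.4) {
  nodes <- c(paste0("w", seq_len(p_well)), paste0("d", seq_len(p_dis)),
             paste0("c", seq_len(p_conf)))
  community <- c(rep("wellbeing", p_well), rep("disability", p_dis),
                 rep("confounder", p_conf))
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  up <- which(upper.tri(W))
  on <- up[runif(length(up)) < density]
  W[on] <- runif(length(on), -0.3, 0.4)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  bridgenet:::new_network_model(
    weights = W,
    communities = tibble::tibble(node = nodes, community = community),
    provenance = list(lambda = 0, gamma = 0.5, n = NA_integer_, ebic = NA_real_))
}

# latent-scale survey: Gaussian node values from a known partial matrix
latent_survey <- function(partial, n, seed, weights = NULL) {
  K <- partial_to_precision(partial)
  Sigma <- cov2cor(solve(K))
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * ncol(partial)), n) %*% chol(Sigma)
    colnames(X) <- colnames(partial)
    d <- tibble::as_tibble(as.data.frame(X))
    d$weight <- if (is.null(weights)) rep(1, n) else weights
    d
  })
}

# 18-node CFM truth with the well-being pair raised to a strong 0.4 edge
strong_edge_truth <- function() {
  nodes <- cfm_communities()
  P <- bridgenet:::edges_to_partial(nodes$node, bridgenet:::cfm_true_edges())
  P["depression", "anxiety"] <- P["anxiety", "depression"] <- 0.4
  P
}
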