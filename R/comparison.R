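#' Permutation comparison of two group networks
#'
#' Estimates one network per group with an identical estimator and tests
#' three null hypotheses by permuting group labels (respondents keep their
#' weights and responses; only labels shuffle):
#' \itemize{
#'   \item global strength invariance — `s_diff = |S_1 - S_2|`, the absolute
#'     difference of the weighted absolute edge sums;
#'   \item network structure invariance — `m_stat = max |W_1 - W_2|`, the
#'     largest absolute edge-wise difference;
#'   \item per-node bridge-expected-influence differences (two-sided on
#'     `|bei_diff|`), Benjamini-Hochberg corrected across the bridge nodes.
#' }
#' P-values use the add-one convention `(1 + #permuted >= observed) /
#' (1 + n_permutations)`, so they are never exactly zero.
#'
#' @param data Survey tibble containing both groups.
#' @param group_var Name of the grouping column (e.g. `"gender"`).
#' @param groups Length-2 character giving the two levels to compare
#'   (default: the two levels present).
#' @param communities Community map.
#' @param weights Weight column name.
#' @param config [estimator_config()] shared by every re-estimation.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed.
#' @param bridge The two communities whose bridge nodes are tested.
#' @return A `network_comparison` object; see [glance.network_comparison()]
#'   and [tidy.network_comparison()].
#' @export
network_compare <- function(data, group_var, groups = NULL,
                            communities = cfm_communities(),
                            weights = "weight",
                            config = estimator_config(),
                            n_permutations = 1000, seed = NULL,
                            bridge = c("wellbeing", "disability")) {
  check_schema(data, communities)
  if (!group_var %in% names(data))
    abort(paste0("grouping column not found: ", group_var))
  labels <- as.character(data[[group_var]])
  if (is.null(groups)) {
    groups <- sort(unique(labels))
    if (length(groups) != 2)
      abort("`groups` must name exactly two levels")
  }
  keep <- labels %in% groups
  data <- data[keep, , drop = FALSE]
  labels <- labels[keep]
  nodes <- communities$node
  p <- length(nodes)
  n1 <- sum(labels == groups[1]); n2 <- sum(labels == groups[2])
  if (n1 < p || n2 < p)
    abort(sprintf(
      "group '%s' has %d respondents but the network has %d nodes; %s",
      if (n1 < p) groups[1] else groups[2], min(n1, n2), p,
      "refusing to estimate a network from fewer cases than nodes"))

  X <- as.matrix(data[nodes]); storage.mode(X) <- "double"
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(data[[weights]])
  comm <- community_lookup(communities)[nodes]
  bridge_idx <- which(comm %in% bridge)
  bridge_nodes <- nodes[bridge_idx]

  stat_fun <- function(lab) {
    i1 <- lab == groups[1]
    f1 <- estimate_W(X[i1, , drop = FALSE], w[i1], config)
    f2 <- estimate_W(X[!i1, , drop = FALSE], w[!i1], config)
    b1 <- bei_vector(f1$W, comm, bridge[1], bridge[2])[bridge_idx]
    b2 <- bei_vector(f2$W, comm, bridge[1], bridge[2])[bridge_idx]
    list(s1 = global_strength(f1$W), s2 = global_strength(f2$W),
         m = max(abs(f1$W - f2$W)), bei1 = b1, bei2 = b2,
         W1 = f1$W, W2 = f2$W)
  }

  local_seed(seed)
  obs <- stat_fun(labels)
  s_diff_obs <- abs(obs$s1 - obs$s2)
  bei_diff_obs <- obs$bei1 - obs$bei2

  s_null <- m_null <- numeric(n_permutations)
  bei_null <- matrix(NA_real_, n_permutations, length(bridge_idx),
                     dimnames = list(NULL, bridge_nodes))
  for (b in seq_len(n_permutations)) {
    perm <- stat_fun(sample(labels))
    s_null[b] <- abs(perm$s1 - perm$s2)
    m_null[b] <- perm$m
    bei_null[b, ] <- perm$bei1 - perm$bei2
  }
  p_global <- (1 + sum(s_null >= s_diff_obs)) / (1 + n_permutations)
  p_structure <- (1 + sum(m_null >= obs$m)) / (1 + n_permutations)
  p_raw <- vapply(seq_along(bridge_idx), function(j)
    (1 + sum(abs(bei_null[, j]) >= abs(bei_diff_obs[j]))) /
      (1 + n_permutations), numeric(1))
  p_bh <- bh_adjust(p_raw)

  structure(
    list(
      groups = groups, group_var = group_var,
      s_group1 = obs$s1, s_group2 = obs$s2, s_diff = s_diff_obs,
      p_global = p_global, m_stat = obs$m, p_structure = p_structure,
      nodes = tibble::tibble(
        node = bridge_nodes, community = unname(comm[bridge_idx]),
        bei_group1 = unname(obs$bei1), bei_group2 = unname(obs$bei2),
        bei_diff = unname(bei_diff_obs), p_raw = p_raw, p_bh = p_bh),
      null = list(s_diff = s_null, m_stat = m_null, bei_diff = bei_null),
      networks = list(obs$W1, obs$W2),
      n_permutations = n_permutations, seed = seed,
      n_group = c(n1, n2), alpha = 0.05),
    class = "network_comparison"
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values `p_(i) * m / i` with cumulative-minimum
#' monotonicity, capped at 1, returned in input order (delegates to
#' [stats::p.adjust()] after validation).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04))
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    abort("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("Network comparison: %s = %s vs %s (n = %d / %d, %d permutations)\n",
              x$group_var, x$groups[1], x$groups[2],
              x$n_group[1], x$n_group[2], x$n_permutations))
  cat(sprintf("  global strength: %.3f vs %.3f (diff %.3f, p = %.4g)\n",
              x$s_group1, x$s_group2, x$s_diff, x$p_global))
  cat(sprintf("  structure invariance M: %.3f (p = %.4g)\n",
              x$m_stat, x$p_structure))
  sig <- x$nodes$node[x$nodes$p_bh < x$alpha]
  cat("  bridge nodes with BH-adjusted p <", x$alpha, ":",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Tidiers for permutation network comparisons
#'
#' `tidy()` gives the per-node bridge-influence tests; `glance()` the global
#' and structure invariance statistics.
#'
#' @param x A `network_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.network_comparison <- function(x, ...) x$nodes

#' @rdname tidy.network_comparison
#' @export
glance.network_comparison <- function(x, ...) {
  tibble::tibble(
    s_group1 = x$s_group1, s_group2 = x$s_group2, s_diff = x$s_diff,
    p_global = x$p_global, m_stat = x$m_stat, p_structure = x$p_structure,
    n_permutations = x$n_permutations
  )
}

#' Serialize a comparison result
#'
#' JSON report of the invariance tests plus a per-node CSV.
#'
#' @param cmp A `network_comparison`.
#' @param basename Path prefix: writes `<basename>.json` and
#'   `<basename>_nodes.csv`.
#' @export
write_comparison <- function(cmp, basename) {
  stopifnot(inherits(cmp, "network_comparison"))
  jsonlite::write_json(
    list(group_var = cmp$group_var, groups = cmp$groups,
         n_group = cmp$n_group,
         s_group1 = cmp$s_group1, s_group2 = cmp$s_group2,
         s_diff = cmp$s_diff, p_global = cmp$p_global,
         m_stat = cmp$m_stat, p_structure = cmp$p_structure,
         n_permutations = cmp$n_permutations, seed = cmp$seed),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(cmp$nodes, paste0(basename, "_nodes.csv"), row.names = FALSE)
  invisible(basename)
}
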