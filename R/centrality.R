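#' Node centralities: expected influence and bridge expected influence
#'
#' Expected influence (EI) of a node is the signed sum of its incident edge
#' weights. One-step bridge expected influence (BEI) is the signed sum of a
#' node's edges that cross between the two bridge communities (well-being
#' and disability by default): edges within a node's own community and edges
#' to confounders are excluded. Confounder nodes sit outside the bridge
#' definition, so their BEI is reported as `NA`, not zero.
#'
#' @param net A `network_model` with a community map.
#' @param bridge Length-2 character: the two communities bridged.
#' @return A tibble `node`, `community`, `ei`, `bei`.
#' @export
#' @examples
#' surv <- simulate_survey(cfm_spec(n_per_group = 300, missing_rate = 0), seed = 1)
#' net <- estimate_network(surv, config = estimator_config(n_lambda = 20))
#' centrality(net)
centrality <- function(net, bridge = c("wellbeing", "disability")) {
  ei <- expected_influence(net)
  bei <- bridge_expected_influence(net, bridge[1], bridge[2])
  dplyr::left_join(ei, bei[c("node", "bei")], by = "node")
}

#' @rdname centrality
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "network_model"))
  comm <- if (!is.null(net$communities))
    community_lookup(net$communities)[net$node_names] else NA_character_
  tibble::tibble(
    node = net$node_names,
    community = unname(comm),
    ei = unname(rowSums(net$weights))
  )
}

#' @rdname centrality
#' @param from,to Community names of the two bridged communities.
#' @export
bridge_expected_influence <- function(net, from = "wellbeing",
                                      to = "disability") {
  stopifnot(inherits(net, "network_model"))
  if (is.null(net$communities))
    abort("network has no community map; supply one to estimate_network()")
  comm <- community_lookup(net$communities)[net$node_names]
  for (cm in c(from, to))
    if (!cm %in% comm)
      abort(paste0("unknown or empty community: ", cm))
  bei <- bei_vector(net$weights, comm, from, to)
  keep <- comm %in% c(from, to)
  tibble::tibble(
    node = net$node_names[keep],
    community = unname(comm[keep]),
    bei = unname(bei[keep])
  )
}

# signed cross-community sums on a raw weights matrix; NA outside the two
# bridge communities
bei_vector <- function(W, comm, from, to) {
  out <- rep(NA_real_, nrow(W))
  names(out) <- rownames(W)
  i_from <- which(comm == from)
  i_to <- which(comm == to)
  out[i_from] <- rowSums(W[i_from, i_to, drop = FALSE])
  out[i_to] <- rowSums(W[i_to, i_from, drop = FALSE])
  out
}

#' Global strength of a network
#'
#' The weighted absolute sum of all edges: `sum_{u < v} |W[u, v]|`.
#'
#' @param net A `network_model` (or a bare weights matrix).
#' @return A single number.
#' @export
global_strength <- function(net) {
  W <- if (inherits(net, "network_model")) net$weights else as.matrix(net)
  sum(abs(W[upper.tri(W)]))
}

#' Write a centrality table as CSV
#'
#' Columns: node, community, ei, bei (empty for confounders).
#'
#' @param centrality_table Tibble from [centrality()].
#' @param path Output CSV path.
#' @export
write_centrality <- function(centrality_table, path) {
  write.csv(centrality_table, path, row.names = FALSE, na = "")
  invisible(path)
}
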