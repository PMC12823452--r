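#' Default Child Functioning Module node set and community map
#'
#' The analysis network has 18 nodes in three declared communities: two
#' mental-well-being nodes (caregiver-reported signs of depression and
#' anxiety, 5-point frequency scale), ten functional-difficulty domains
#' (4-point severity scale), and six confounders (sociodemographic
#' covariates treated as ordinal codes).
#'
#' @return A tibble with columns `node` (identifier), `community`
#'   (`"wellbeing"`, `"disability"` or `"confounder"`) and `levels`
#'   (number of ordinal categories used by the synthetic generator).
#' @export
#' @examples
#' cfm_communities()
cfm_communities <- function() {
  tibble::tibble(
    node = c(
      "depression", "anxiety",
      "seeing", "hearing", "walking", "self_care", "communication",
      "learning", "remembering_concentrating", "accepting_change",
      "behaviour_control", "making_friends",
      "age", "education", "wealth", "residence", "econ_activity",
      "house_chores"
    ),
    community = c(
      rep("wellbeing", 2L), rep("disability", 10L), rep("confounder", 6L)
    ),
    levels = c(
      5L, 5L, rep(4L, 10L), 13L, 3L, 5L, 2L, 5L, 5L
    )
  )
}

#' @rdname cfm_communities
#' @export
cfm_node_names <- function() cfm_communities()$node

# named community vector keyed by node
community_lookup <- function(communities) {
  stopifnot(is.data.frame(communities),
            all(c("node", "community") %in% names(communities)))
  if (anyDuplicated(communities$node))
    abort("community map contains duplicated node names")
  setNames(as.character(communities$community), communities$node)
}

# validate that `data` has every node column of the community map
check_schema <- function(data, communities) {
  missing_cols <- setdiff(communities$node, names(data))
  if (length(missing_cols))
    abort(paste0("data is missing node columns declared in the community map: ",
                 paste(missing_cols, collapse = ", ")))
  invisible(TRUE)
}
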