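#' Convert a partial-correlation matrix to a precision matrix
#'
#' Inverts the standard map `pcor_ij = -k_ij / sqrt(k_ii * k_jj)` under the
#' unit-diagonal convention (`k_ii = 1`), so `k_ij = -pcor_ij`. The result
#' must be positive definite for the partial matrix to describe a valid
#' Gaussian graphical model.
#'
#' @param partial Symmetric matrix of partial correlations, zero diagonal,
#'   entries in (-1, 1).
#' @return The precision matrix `K` with unit diagonal.
#' @export
#' @examples
#' partial_to_precision(matrix(c(0, .5, .5, 0), 2))
partial_to_precision <- function(partial) {
  partial <- as.matrix(partial)
  if (!isSymmetric(unname(partial), tol = 1e-10))
    abort("partial matrix must be symmetric")
  if (any(abs(diag(partial)) > 1e-12))
    abort("partial matrix must have a zero diagonal")
  if (any(abs(partial) >= 1))
    abort("partial correlations must lie strictly in (-1, 1)")
  K <- -partial
  diag(K) <- 1
  ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0)
    abort(paste0("implied precision matrix is not positive definite ",
                 "(minimum eigenvalue ", signif(ev, 4), ")"))
  K
}

#' Partial correlations implied by a precision matrix
#'
#' @param precision Symmetric positive-definite precision matrix.
#' @return Matrix of partial correlations `-k_ij/sqrt(k_ii k_jj)` with zero
#'   diagonal.
#' @export
precision_to_partial <- function(precision) {
  precision <- as.matrix(precision)
  d <- 1 / sqrt(diag(precision))
  P <- -(precision * outer(d, d))
  diag(P) <- 0
  (P + t(P)) / 2
}

# build a symmetric zero-diagonal matrix from an edge list
edges_to_partial <- function(nodes, edges) {
  p <- length(nodes)
  P <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    if (!a %in% nodes || !b %in% nodes)
      abort(paste0("edge references unknown node: ", a, " -- ", b))
    P[a, b] <- P[b, a] <- edges$weight[i]
  }
  P
}

# Default ground-truth edges for the CFM-like generator: a sparse structure
# with an associated well-being pair, bridge edges from well-being into the
# social/cognitive disability domains, a connected disability community and
# a loosely connected confounder block.
cfm_true_edges <- function() {
  tibble::tribble(
    ~from,          ~to,                         ~weight,
    "depression",   "anxiety",                    0.35,
    "anxiety",      "accepting_change",           0.12,
    "anxiety",      "remembering_concentrating",  0.10,
    "depression",   "making_friends",             0.12,
    "depression",   "behaviour_control",          0.10,
    "seeing",       "hearing",                    0.15,
    "seeing",       "walking",                    0.10,
    "walking",      "self_care",                  0.20,
    "self_care",    "communication",              0.15,
    "communication","learning",                   0.25,
    "communication","making_friends",             0.15,
    "learning",     "remembering_concentrating",  0.25,
    "remembering_concentrating", "accepting_change", 0.20,
    "accepting_change", "behaviour_control",      0.25,
    "behaviour_control", "making_friends",        0.20,
    "age",          "education",                  0.30,
    "age",          "econ_activity",              0.15,
    "wealth",       "residence",                  0.25,
    "econ_activity","house_chores",               0.20,
    "education",    "learning",                  -0.10,
    "wealth",       "seeing",                    -0.08,
    "age",          "walking",                    0.08
  )
}

# default per-node threshold quantiles (cumulative category probabilities,
# dropping the final 1): most mass in the lowest severity code, mirroring
# the right-skew typical of functional-difficulty items
default_threshold_probs <- function(node, levels) {
  known <- list(
    depression   = c(0.40, 0.62, 0.80, 0.92),
    anxiety      = c(0.40, 0.62, 0.80, 0.92),
    education    = c(0.35, 0.75),
    wealth       = c(0.2, 0.4, 0.6, 0.8),
    residence    = 0.6,
    econ_activity = c(0.50, 0.70, 0.85, 0.95),
    house_chores = c(0.35, 0.60, 0.80, 0.93)
  )
  if (node %in% names(known)) return(known[[node]])
  if (levels == 4L) return(c(0.60, 0.85, 0.95))   # disability severity items
  seq_len(levels - 1L) / levels                    # equal-frequency fallback
}

#' Specify a synthetic ordinal-survey generator
#'
#' Bundles everything the generator needs: the node set with ordinal level
#' counts and latent thresholds, and one ground-truth partial-correlation
#' matrix per respondent group. Ordinal codes arise by thresholding a latent
#' multivariate Gaussian whose precision matrix is implied by each group's
#' partial matrix; thresholds live on the standard-normal scale so they are
#' interpretable as marginal quantiles.
#'
#' @param groups A data frame with one row per group: any number of grouping
#'   columns (e.g. `gender`, `age_group`), an `n` column (respondents per
#'   group) and a `partial` list-column of symmetric zero-diagonal true
#'   partial-correlation matrices (nodes in `nodes$node` order).
#' @param nodes Node table as from [cfm_communities()]; a `thresholds`
#'   list-column may supply per-node cut-points, otherwise defaults with
#'   most mass in the lowest code are used.
#' @param weight_meanlog,weight_sdlog Log-normal parameters of the sampling
#'   weights (normalized to mean 1 within each group).
#' @param missing_rate Fraction of node cells masked completely at random.
#' @return An object of class `synthetic_spec`.
#' @seealso [cfm_spec()] for the ready-made default, [simulate_survey()].
#' @export
synthetic_spec <- function(groups, nodes = cfm_communities(),
                           weight_meanlog = 0, weight_sdlog = 0.5,
                           missing_rate = 0.09) {
  stopifnot(is.data.frame(groups), is.data.frame(nodes))
  if (!all(c("n", "partial") %in% names(groups)))
    abort("`groups` needs columns `n` and `partial`")
  group_vars <- setdiff(names(groups), c("n", "partial"))
  if (!length(group_vars)) abort("`groups` needs at least one grouping column")
  if (missing_rate < 0 || missing_rate >= 1)
    abort("`missing_rate` must lie in [0, 1)")
  if (weight_sdlog < 0) abort("`weight_sdlog` must be non-negative")
  if (any(groups$n < 2)) abort("each group needs at least 2 respondents")

  if (!"thresholds" %in% names(nodes))
    nodes$thresholds <- purrr::map2(nodes$node, nodes$levels,
      ~ qnorm(default_threshold_probs(.x, .y)))
  purrr::pwalk(list(nodes$node, nodes$levels, nodes$thresholds),
    function(nd, lv, th) {
      if (length(th) != lv - 1L)
        abort(paste0("node ", nd, ": needs ", lv - 1L, " thresholds, got ",
                     length(th)))
      if (any(diff(th) <= 0))
        abort(paste0("node ", nd, ": thresholds must be strictly increasing"))
    })
  for (i in seq_len(nrow(groups))) {
    P <- groups$partial[[i]]
    if (!identical(dim(P), c(nrow(nodes), nrow(nodes))))
      abort("each true partial matrix must be p x p for the node set")
    partial_to_precision(P)  # validates symmetry, range, positive definiteness
  }
  structure(
    list(groups = groups, group_vars = group_vars, nodes = nodes,
         weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog,
         missing_rate = missing_rate),
    class = "synthetic_spec"
  )
}

#' Ready-made CFM-like synthetic study specification
#'
#' Four groups crossing gender (female/male) with developmental stage
#' (children 5-9 vs adolescents 10-17). All groups share a sparse base
#' network; group contrasts are injected by editing named bridge edges:
#' males carry a stronger anxiety-disability bridge, adolescents a stronger
#' depression-disability bridge. Edit lists are explicit so power
#' experiments for the comparison test are scriptable.
#'
#' @param n_per_group Respondents per group.
#' @param missing_rate Completely-at-random missingness fraction (default
#'   0.09, matching the missing-data share the cohort design anticipates).
#' @param edge_edits Optional tibble of edits (`group` regular expression,
#'   `from`, `to`, `delta`) applied on top of the defaults; pass
#'   `edge_edits = NULL` and `use_default_edits = FALSE` for identical
#'   group truths.
#' @param use_default_edits Apply the built-in gender/age edits?
#' @inheritParams synthetic_spec
#' @return A `synthetic_spec`.
#' @export
#' @examples
#' spec <- cfm_spec(n_per_group = 200, missing_rate = 0)
#' surv <- simulate_survey(spec, seed = 1)
cfm_spec <- function(n_per_group = 2000, missing_rate = 0.09,
                     edge_edits = NULL, use_default_edits = TRUE,
                     weight_meanlog = 0, weight_sdlog = 0.5) {
  nodes <- cfm_communities()
  base <- edges_to_partial(nodes$node, cfm_true_edges())
  edits <- if (use_default_edits) tibble::tribble(
    ~group,        ~from,        ~to,                ~delta,
    "male",        "anxiety",    "accepting_change",  0.06,
    "male",        "anxiety",    "hearing",           0.05,
    "male",        "depression", "self_care",        -0.04,
    "adolescent",  "depression", "making_friends",    0.06,
    "adolescent",  "depression", "behaviour_control", 0.05
  ) else NULL
  if (!is.null(edge_edits)) edits <- dplyr::bind_rows(edits, edge_edits)

  groups <- tidyr::expand_grid(gender = c("female", "male"),
                               age_group = c("child", "adolescent"))
  groups$n <- n_per_group
  groups$partial <- purrr::map2(groups$gender, groups$age_group, function(g, a) {
    P <- base
    if (!is.null(edits)) {
      label <- paste(g, a)
      for (i in seq_len(nrow(edits))) {
        if (grepl(edits$group[i], label)) {
          P[edits$from[i], edits$to[i]] <-
            P[edits$to[i], edits$from[i]] <-
            P[edits$from[i], edits$to[i]] + edits$delta[i]
        }
      }
    }
    P
  })
  synthetic_spec(groups, nodes = nodes, weight_meanlog = weight_meanlog,
                 weight_sdlog = weight_sdlog, missing_rate = missing_rate)
}

#' Simulate a CFM-like ordinal survey from a known network
#'
#' For each group, draws a latent multivariate Gaussian with covariance equal
#' to the standardized inverse of the group's precision matrix (unit
#' variances, so thresholds are marginal quantiles), discretizes each node at
#' its thresholds into ordinal codes 1..levels, attaches log-normal sampling
#' weights normalized to mean 1 per group, and masks node cells completely at
#' random. Fully reproducible from `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed (the caller's RNG state is restored on exit).
#' @param return_latent Keep the pre-discretization latent matrix as
#'   attribute `"latent"` (used for estimator validation)?
#' @return A tibble: `id`, grouping columns, `weight`, one ordinal column per
#'   node. The spec is attached as attribute `"spec"`.
#' @export
simulate_survey <- function(spec, seed = NULL, return_latent = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  local_seed(seed)
  nodes <- spec$nodes
  p <- nrow(nodes)
  out <- vector("list", nrow(spec$groups))
  latents <- if (return_latent) vector("list", nrow(spec$groups))
  for (g in seq_len(nrow(spec$groups))) {
    n <- spec$groups$n[g]
    K <- partial_to_precision(spec$groups$partial[[g]])
    Sigma <- stats::cov2cor(solve(K))
    Z <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
    colnames(Z) <- nodes$node
    codes <- Z
    for (j in seq_len(p))
      codes[, j] <- findInterval(Z[, j], nodes$thresholds[[j]]) + 1
    w <- rlnorm(n, spec$weight_meanlog, spec$weight_sdlog)
    w <- w / mean(w)
    if (spec$missing_rate > 0) {
      mask <- matrix(runif(n * p) < spec$missing_rate, n, p)
      codes[mask] <- NA_real_
    }
    tab <- tibble::as_tibble(as.data.frame(codes))
    for (v in spec$group_vars) tab[[v]] <- spec$groups[[v]][g]
    tab$weight <- w
    out[[g]] <- tab[c(spec$group_vars, "weight", nodes$node)]
    if (return_latent) latents[[g]] <- Z
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::bind_cols(tibble::tibble(id = seq_len(nrow(res))), res)
  attr(res, "spec") <- spec
  if (return_latent) attr(res, "latent") <- do.call(rbind, latents)
  res
}

#' Write / read a survey table as CSV with a JSON sidecar
#'
#' The CSV holds one row per respondent (missing cells empty); the sidecar
#' records the grouping columns, node order, community map and — when the
#' table came from [simulate_survey()] — the generator's true partial
#' matrices and parameters.
#'
#' @param data Survey tibble.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @param communities Community map for the sidecar.
#' @export
write_survey <- function(data, path, communities = cfm_communities()) {
  write.csv(data, path, row.names = FALSE, na = "")
  spec <- attr(data, "spec")
  meta <- list(
    node = communities$node,
    community = communities$community,
    columns = names(data)
  )
  if (!is.null(spec)) {
    meta$generator <- list(
      group_vars = spec$group_vars,
      groups = spec$groups[spec$group_vars],
      n = spec$groups$n,
      missing_rate = spec$missing_rate,
      weight_meanlog = spec$weight_meanlog,
      weight_sdlog = spec$weight_sdlog,
      true_partial = purrr::map(spec$groups$partial, ~ unname(as.matrix(.x))),
      thresholds = spec$nodes$thresholds
    )
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
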