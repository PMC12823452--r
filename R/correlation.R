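#' Weighted correlation matrix from ordinal survey data
#'
#' Estimates the node-by-node correlation matrix using per-respondent
#' sampling weights, on available cases: each pair's correlation is computed
#' over the rows where both nodes are observed, with the weights
#' renormalized within that pair (`missing = "pairwise"`, the default), or
#' over the rows complete on all nodes (`"listwise"`). `method = "spearman"`
#' first replaces each column by weighted mid-ranks of its observed values,
#' then applies the same weighted-Pearson machinery.
#'
#' @param data Survey tibble (one row per respondent).
#' @param nodes Character vector of node columns (default: the CFM map).
#' @param weights Name of the weight column, or `NULL` for equal weights.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param missing `"pairwise"` (available cases) or `"listwise"`.
#' @param repair Repair an indefinite pairwise matrix to the nearest
#'   correlation matrix (see [nearest_pd_repair()])?
#' @return A `weighted_corr` object: `matrix` (p x p, unit diagonal),
#'   `n_pairwise` (per-pair available-case counts), `n` (rows with at least
#'   one observed node — the case count used by EBIC downstream), `method`,
#'   `missing`, `repaired`.
#' @export
#' @examples
#' surv <- simulate_survey(cfm_spec(n_per_group = 100, missing_rate = 0), seed = 1)
#' wc <- weighted_correlation(surv)
#' round(wc$matrix[1:3, 1:3], 2)
weighted_correlation <- function(data, nodes = cfm_node_names(),
                                 weights = "weight",
                                 method = c("pearson", "spearman"),
                                 missing = c("pairwise", "listwise"),
                                 repair = TRUE) {
  method <- match.arg(method)
  missing <- match.arg(missing)
  miss_cols <- setdiff(nodes, names(data))
  if (length(miss_cols))
    abort(paste0("missing node columns: ", paste(miss_cols, collapse = ", ")))
  X <- as.matrix(data[nodes])
  storage.mode(X) <- "double"
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(data[[weights]])
  if (any(!is.finite(w)) || any(w <= 0))
    abort("sampling weights must be strictly positive and finite")

  res <- wcorr_matrix(X, w, method = method, missing = missing)
  repaired <- FALSE
  if (repair) {
    rep_out <- nearest_pd_repair(res$R)
    res$R <- rep_out$matrix
    repaired <- rep_out$repaired
  }
  structure(
    list(matrix = res$R, n_pairwise = res$n_pairwise, n = res$n,
         method = method, missing = missing, repaired = repaired,
         nodes = nodes),
    class = "weighted_corr"
  )
}

#' @export
print.weighted_corr <- function(x, ...) {
  cat("Weighted", x$method, "correlation matrix (", x$missing, "deletion)\n")
  cat("  nodes:", length(x$nodes), "  n:", x$n,
      "  PD-repaired:", x$repaired, "\n")
  invisible(x)
}

# weighted mid-rank of the observed entries of x:
# rank_i = sum(w[x < x_i]) + (sum(w[x == x_i]) + w_i) / 2
weighted_rank <- function(x, w) {
  out <- rep(NA_real_, length(x))
  obs <- which(!is.na(x))
  xo <- x[obs]; wo <- w[obs]
  o <- order(xo)
  xs <- xo[o]; ws <- wo[o]
  below <- cumsum(c(0, ws))[seq_along(ws)]   # weight strictly before position
  grp <- cumsum(c(TRUE, diff(xs) != 0))      # tie groups
  gb <- tapply(below, grp, min)              # weight below each tie group
  gw <- tapply(ws, grp, sum)                 # weight within each tie group
  r <- gb[grp] + (gw[grp] + ws) / 2
  out[obs[o]] <- r
  out
}

# core estimator; returns list(R, n_pairwise, n)
wcorr_matrix <- function(X, w, method = "pearson", missing = "pairwise") {
  p <- ncol(X)
  if (method == "spearman")
    for (j in seq_len(p)) X[, j] <- weighted_rank(X[, j], w)
  if (missing == "listwise") {
    keep <- complete.cases(X)
    if (sum(keep) < 3) abort("fewer than 3 complete cases for listwise deletion")
    X <- X[keep, , drop = FALSE]
    w <- w[keep]
  }
  n_used <- sum(rowSums(!is.na(X)) > 0)
  if (!anyNA(X)) {
    R <- wcorr_complete(X, w)
    npair <- matrix(nrow(X), p, p)
  } else {
    pw <- wcorr_pairwise(X, w)
    R <- pw$R
    npair <- pw$npair
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  list(R = R, n_pairwise = npair, n = n_used)
}

wcorr_complete <- function(X, w) {
  sw <- sum(w)
  mu <- colSums(X * w) / sw
  Xc <- sweep(X, 2, mu)
  V <- crossprod(Xc * w, Xc) / sw
  v <- diag(V)
  if (any(v <= 1e-14)) {
    bad <- colnames(X)[v <= 1e-14]
    abort(paste0("zero weighted variance in node(s): ",
                 paste(bad, collapse = ", ")))
  }
  R <- V / sqrt(outer(v, v))
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R
}

# Vectorized available-case weighted correlations: all pairwise moments via
# cross-products of masked matrices, weights renormalized per pair.
wcorr_pairwise <- function(X, w) {
  M <- !is.na(X)
  storage.mode(M) <- "double"
  X0 <- X; X0[is.na(X0)] <- 0
  Wm <- M * w
  SW  <- crossprod(Wm, M)          # sum of w over jointly observed rows
  npair <- crossprod(M, M)
  off <- upper.tri(npair)
  if (any(npair[off] < 3)) {
    idx <- which(npair < 3 & off, arr.ind = TRUE)[1, ]
    abort(paste0("fewer than 3 available cases for pair ",
                 colnames(X)[idx[1]], " -- ", colnames(X)[idx[2]]))
  }
  SX  <- crossprod(X0 * w, M)      # (j,k): sum w x_j over joint rows
  SXY <- crossprod(X0 * w, X0)     # sum w x_j x_k
  SX2 <- crossprod(X0^2 * w, M)    # sum w x_j^2 over joint rows
  Mjk <- SX / SW                   # mean of j within pair (j,k)
  Cv  <- SXY / SW - Mjk * t(Mjk)
  Vjk <- SX2 / SW - Mjk^2          # variance of j within pair (j,k)
  if (any(Vjk <= 1e-14)) {
    idx <- which(Vjk <= 1e-14, arr.ind = TRUE)[1, ]
    abort(paste0("zero weighted variance in node ", colnames(X)[idx[1]],
                 " within its available cases"))
  }
  R <- Cv / sqrt(Vjk * t(Vjk))
  R[R > 1] <- 1; R[R < -1] <- -1
  diag(R) <- 1
  R <- (R + t(R)) / 2
  list(R = R, npair = npair)
}

#' Nearest correlation-matrix repair
#'
#' Pairwise deletion can produce an indefinite "correlation" matrix. This
#' projects a symmetric matrix onto the nearest correlation matrix (unit
#' diagonal, eigenvalues bounded away from zero) using alternating
#' projections with Dykstra correction ([Matrix::nearPD()]), then enforces
#' an eigenvalue floor by minimal uniform shrinkage towards the identity.
#'
#' @param mat Symmetric matrix.
#' @param eig_floor Minimum eigenvalue required of the output (default 1e-8).
#' @return List with `matrix` (repaired) and `repaired` (`TRUE` if the input
#'   was altered beyond 1e-10).
#' @export
nearest_pd_repair <- function(mat, eig_floor = 1e-8) {
  mat <- as.matrix(mat)
  if (!isSymmetric(unname(mat), tol = 1e-8))
    abort("input to nearest_pd_repair must be symmetric")
  mat <- (mat + t(mat)) / 2
  ev_min <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min >= eig_floor)
    return(list(matrix = mat, repaired = FALSE))
  out <- as.matrix(Matrix::nearPD(mat, corr = TRUE, do2eigen = TRUE,
                                  posd.tol = 1e-6, maxit = 200)$mat)
  ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < eig_floor) {
    delta <- (eig_floor - ev) / (1 - eig_floor)
    out <- (out + delta * diag(nrow(out))) / (1 + delta)
  }
  dimnames(out) <- dimnames(mat)
  changed <- max(abs(out - mat)) > 1e-10
  list(matrix = out, repaired = changed)
}

#' Serialize / read a correlation matrix
#'
#' Square CSV with node names as header row and first column, plus a JSON
#' metadata sidecar (method, missing policy, case count, repair flag).
#'
#' @param wc A `weighted_corr`.
#' @param path CSV path; metadata goes to `<path>.meta.json`.
#' @export
write_correlation <- function(wc, path) {
  stopifnot(inherits(wc, "weighted_corr"))
  write.csv(wc$matrix, path, row.names = TRUE)
  jsonlite::write_json(
    list(method = wc$method, missing = wc$missing, n = wc$n,
         repaired = wc$repaired),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
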