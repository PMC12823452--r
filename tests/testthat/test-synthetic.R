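test_that("partial_to_precision implements the sign-flip map and round-trips", {
  # independence: zero partials -> identity precision
  expect_equal(partial_to_precision(matrix(0, 18, 18)), diag(18))
  # two nodes at pcor 0.5
  expect_equal(partial_to_precision(matrix(c(0, .5, .5, 0), 2)),
               matrix(c(1, -.5, -.5, 1), 2))
  # random sparse 5-node matrices against the dense inversion oracle
  withr::with_seed(11, for (rep in 1:20) {
    P <- matrix(0, 5, 5)
    idx <- sample(which(upper.tri(P)), 4)
    P[idx] <- runif(4, -0.3, 0.3)
    P <- P + t(P)
    K <- partial_to_precision(P)
    expect_equal(partial_oracle(solve(K)), P, tolerance = 1e-12)
    expect_equal(precision_to_partial(K), P, tolerance = 1e-12)
  })
})

test_that("invalid partial matrices are rejected with a diagnostic", {
  expect_error(partial_to_precision(matrix(c(0, .2, .3, 0), 2)), "symmetric")
  expect_error(partial_to_precision(diag(2)), "zero diagonal")
  P <- matrix(0.9, 3, 3); diag(P) <- 0
  expect_error(partial_to_precision(P), "eigenvalue")
})

test_that("generator respects missingness settings and is seed-deterministic", {
  spec0 <- cfm_spec(n_per_group = 60, missing_rate = 0)
  surv0 <- simulate_survey(spec0, seed = 3)
  expect_false(anyNA(surv0[cfm_node_names()]))
  expect_true(all(surv0$weight > 0))

  spec <- cfm_spec(n_per_group = 500, missing_rate = 0.09)
  surv <- simulate_survey(spec, seed = 3)
  expect_identical(surv, simulate_survey(spec, seed = 3))
  # empirical missing fraction within 3 binomial SEs of the target
  n_cells <- nrow(surv) * length(cfm_node_names())
  frac <- mean(is.na(surv[cfm_node_names()]))
  se <- sqrt(0.09 * 0.91 / n_cells)
  expect_lt(abs(frac - 0.09), 3 * se)
  # all observed codes in the valid per-node range
  comm <- cfm_communities()
  for (i in seq_len(nrow(comm))) {
    x <- surv[[comm$node[i]]]
    expect_true(all(x[!is.na(x)] %in% seq_len(comm$levels[i])))
  }
})

test_that("marginal category frequencies match the Gaussian orthant probabilities", {
  nodes <- cfm_communities()
  groups <- tibble::tibble(group = "all", n = 10000,
                           partial = list(matrix(0, 18, 18)))
  spec <- synthetic_spec(groups, nodes = nodes, missing_rate = 0)
  surv <- simulate_survey(spec, seed = 9)
  for (i in seq_len(nrow(nodes))) {
    th <- spec$nodes$thresholds[[i]]
    expected <- diff(c(0, pnorm(th), 1))
    observed <- tabulate(surv[[nodes$node[i]]], nbins = nodes$levels[i]) / 10000
    expect_lt(max(abs(observed - expected)), 0.02)
  }
})

test_that("discretized pair frequencies follow the implied bivariate normal", {
  # two ordinal nodes with a single latent partial correlation of 0.4;
  # oracle = numerically integrated bivariate-normal rectangle probabilities
  nodes <- tibble::tibble(node = c("a", "b"),
                          community = c("wellbeing", "disability"),
                          levels = c(3L, 3L),
                          thresholds = list(qnorm(c(0.5, 0.8)),
                                            qnorm(c(0.6, 0.9))))
  P <- matrix(c(0, .4, .4, 0), 2)
  groups <- tibble::tibble(group = "g", n = 20000, partial = list(P))
  spec <- synthetic_spec(groups, nodes = nodes, missing_rate = 0)
  surv <- simulate_survey(spec, seed = 13)

  K <- partial_to_precision(P)
  r <- cov2cor(solve(K))[1, 2]
  # P(X <= a, Y <= b) under correlation r by 1-D quadrature
  pbiv <- function(a, b) {
    if (!is.finite(a) && a > 0) return(pnorm(b))
    integrate(function(x) pnorm((b - r * x) / sqrt(1 - r^2)) * dnorm(x),
              -Inf, a, rel.tol = 1e-10)$value
  }
  cut_a <- c(-Inf, nodes$thresholds[[1]], Inf)
  cut_b <- c(-Inf, nodes$thresholds[[2]], Inf)
  cdf <- outer(cut_a, cut_b, Vectorize(function(a, b) {
    if (a == -Inf || b == -Inf) 0 else if (a == Inf) pnorm(b)
    else if (b == Inf) pnorm(a) else pbiv(a, b)
  }))
  cells <- cdf[-1, -1] - cdf[-1, -4] - cdf[-4, -1] + cdf[-4, -4]
  observed <- table(factor(surv$a, 1:3), factor(surv$b, 1:3)) / 20000
  expect_lt(max(abs(observed - cells)), 0.015)
})

test_that("spec validation catches degenerate settings", {
  nodes <- cfm_communities()
  groups <- tibble::tibble(group = "g", n = 10,
                           partial = list(matrix(0, 18, 18)))
  expect_error(synthetic_spec(groups, nodes, missing_rate = 1), "missing_rate")
  bad_nodes <- nodes
  bad_nodes$thresholds <- purrr::map(nodes$levels, ~ rep(0, .x - 1))
  expect_error(synthetic_spec(groups, nodes = bad_nodes), "increasing")
  expect_error(synthetic_spec(dplyr::mutate(groups, n = 1), nodes),
               "at least 2")
})

test_that("survey CSV round-trips with its JSON sidecar", {
  surv <- small_survey(n = 40, missing_rate = 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey(surv, path)
  back <- read_survey(path)
  expect_equal(as.data.frame(back), as.data.frame(surv),
               ignore_attr = TRUE, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$node, cfm_node_names())
  expect_equal(meta$generator$missing_rate, 0.1)
  expect_equal(dim(meta$generator$true_partial), c(4L, 18L, 18L))
})
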