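test_that("equal weights on complete data reproduce the unweighted matrix", {
  surv <- small_survey(n = 80, missing_rate = 0, seed = 4)
  surv$weight <- 1
  wc <- weighted_correlation(surv)
  expect_equal(unname(wc$matrix),
               unname(cor(as.matrix(surv[cfm_node_names()]))),
               tolerance = 1e-12)
  expect_equal(wc$n, nrow(surv))
  expect_false(wc$repaired)
})

test_that("weighted correlation matches the weighted-moments formula", {
  # 5-row toy with unequal weights, hand-evaluated oracle
  d <- tibble::tibble(x = c(1, 2, 2, 3, 4), y = c(2, 1, 3, 3, 5),
                      w = c(1, 1, 1, 2, 5))
  wc <- weighted_correlation(d, nodes = c("x", "y"), weights = "w")
  xm <- sum(d$w * d$x) / sum(d$w)
  ym <- sum(d$w * d$y) / sum(d$w)
  oracle <- sum(d$w * (d$x - xm) * (d$y - ym)) /
    sqrt(sum(d$w * (d$x - xm)^2) * sum(d$w * (d$y - ym)^2))
  expect_equal(wc$matrix["x", "y"], oracle, tolerance = 1e-12)
})

test_that("a duplicated node correlates with itself at exactly 1", {
  surv <- small_survey(n = 50, missing_rate = 0, seed = 5)
  surv$dup <- surv$seeing
  wc <- weighted_correlation(surv, nodes = c("seeing", "dup", "walking"),
                             repair = FALSE)
  expect_equal(wc$matrix["seeing", "dup"], 1, tolerance = 1e-14)
})

test_that("pairwise and listwise agree exactly on complete data", {
  surv <- small_survey(n = 120, missing_rate = 0, seed = 6)
  pw <- weighted_correlation(surv, missing = "pairwise")
  lw <- weighted_correlation(surv, missing = "listwise")
  expect_equal(pw$matrix, lw$matrix, tolerance = 1e-14)
})

test_that("available-case estimates converge to the complete-data estimate", {
  surv <- small_survey(n = 1000, missing_rate = 0, seed = 7)
  R0 <- weighted_correlation(surv)$matrix
  nodes <- cfm_node_names()
  devs <- purrr::map_dbl(c(0.01, 0.05, 0.10), function(rate) {
    masked <- surv
    withr::with_seed(100 + round(rate * 100), {
      for (j in nodes) masked[[j]][runif(nrow(masked)) < rate] <- NA
    })
    max(abs(weighted_correlation(masked)$matrix - R0))
  })
  expect_lt(devs[1], 0.03)
  expect_lt(devs[2], 0.07)
  expect_lt(devs[3], 0.10)
  expect_lt(devs[1], devs[3])
})

test_that("weighted Pearson on latent values recovers the true correlation", {
  spec <- cfm_spec(n_per_group = 12500, missing_rate = 0,
                   use_default_edits = FALSE)
  surv <- simulate_survey(spec, seed = 8, return_latent = TRUE)
  Z <- attr(surv, "latent")
  d <- tibble::as_tibble(as.data.frame(Z))
  d$weight <- surv$weight
  R <- weighted_correlation(d, nodes = colnames(Z))$matrix
  K <- partial_to_precision(spec$groups$partial[[1]])
  truth <- cov2cor(solve(K))
  expect_lt(max(abs(R - truth)), 0.02)
})

test_that("degenerate inputs raise named errors", {
  d <- tibble::tibble(a = c(1, 2, 3, 4), b = c(1, NA, NA, NA),
                      w = rep(1, 4))
  expect_error(weighted_correlation(d, nodes = c("a", "b"), weights = "w"),
               "available cases")
  d2 <- tibble::tibble(a = c(1, 2, 3, 4), b = rep(2, 4), w = rep(1, 4))
  expect_error(weighted_correlation(d2, nodes = c("a", "b"), weights = "w"),
               "variance.*b")
  d3 <- tibble::tibble(a = 1:4, b = 4:1, w = c(-1, 1, 1, 1))
  expect_error(weighted_correlation(d3, nodes = c("a", "b"), weights = "w"),
               "positive")
})

test_that("weighted mid-ranks reduce to ordinary mid-ranks at unit weights", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, NA, 5)
  r <- bridgenet:::weighted_rank(x, rep(1, length(x)))
  expect_equal(r[!is.na(x)], rank(x[!is.na(x)]))
  expect_true(is.na(r[10]))
  # spearman path runs end to end
  surv <- small_survey(n = 60, missing_rate = 0.05, seed = 9)
  wc <- weighted_correlation(surv, method = "spearman")
  expect_true(all(abs(wc$matrix) <= 1))
  expect_equal(diag(wc$matrix), setNames(rep(1, 18), cfm_node_names()))
})

test_that("nearest_pd_repair returns PD inputs unchanged and fixes indefinite ones", {
  S <- random_pd_corr(5)
  out <- nearest_pd_repair(S)
  expect_false(out$repaired)
  expect_equal(out$matrix, S)

  bad <- matrix(c(1, .9, .9, .9, 1, -.9, .9, -.9, 1), 3)
  expect_lt(min(eigen(bad, only.values = TRUE)$values), 0)
  rep_out <- nearest_pd_repair(bad)
  expect_true(rep_out$repaired)
  expect_gte(min(eigen(rep_out$matrix, only.values = TRUE)$values), 1e-8)
  expect_equal(diag(rep_out$matrix), rep(1, 3), tolerance = 1e-8)

  expect_equal(nearest_pd_repair(diag(4))$matrix, diag(4))
  expect_error(nearest_pd_repair(matrix(rnorm(9), 3)), "symmetric")
})
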