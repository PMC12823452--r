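test_that("a single bootstrap resample collapses the CI to that resample", {
  surv <- small_survey(n = 100, missing_rate = 0, seed = 61)
  bt <- bootstrap_network(surv, config = tiny_config(), n_boot = 1, seed = 2)
  expect_equal(bt$table$lower, bt$table$boot_mean)
  expect_equal(bt$table$upper, bt$table$boot_mean)
  expect_equal(bt$n_failed, 0L)
})

test_that("bootstrap is seed-deterministic with ordered quantiles", {
  surv <- small_survey(n = 120, missing_rate = 0, seed = 62)
  cfg <- tiny_config()
  b1 <- bootstrap_network(surv, config = cfg, n_boot = 25, seed = 9)
  b2 <- bootstrap_network(surv, config = cfg, n_boot = 25, seed = 9)
  expect_equal(b1$table, b2$table)
  expect_true(all(b1$table$lower <= b1$table$boot_mean + 1e-12))
  expect_true(all(b1$table$boot_mean <= b1$table$upper + 1e-12))
  # one row per edge, per node EI, per bridge-node BEI
  expect_equal(unname(table(b1$table$type)[c("edge", "ei", "bei")]),
               c(18 * 17 / 2, 18L, 12L), ignore_attr = TRUE)
  # study default resample count
  expect_equal(eval(formals(bootstrap_network)$n_boot), 5000)
})

test_that("confidence intervals shrink as the sample grows", {
  truth <- strong_edge_truth()
  d_small <- latent_survey(truth, n = 1000, seed = 63)
  d_large <- latent_survey(truth, n = 10000, seed = 64)
  cfg <- tiny_config()
  comm <- cfm_communities()
  b_small <- bootstrap_network(d_small, communities = comm, config = cfg,
                               n_boot = 120, seed = 3)
  b_large <- bootstrap_network(d_large, communities = comm, config = cfg,
                               n_boot = 120, seed = 3)
  width <- function(b) {
    e <- dplyr::filter(b$table, .data$type == "edge",
                       .data$entity == "depression--anxiety")
    e$upper - e$lower
  }
  expect_lt(width(b_large), width(b_small))
})

test_that("the CS coefficient is recomputable from the stored raw draws", {
  surv <- small_survey(n = 75, missing_rate = 0, seed = 65)  # n = 300
  st <- case_dropping_stability(surv, config = tiny_config(),
                                drop_grid = c(0.1, 0.3, 0.5),
                                n_boot = 150, seed = 12)
  expect_equal(st$n_boot_per_proportion, 50)
  expect_true(all(st$draws$correlation >= -1 & st$draws$correlation <= 1,
                  na.rm = TRUE))
  # recompute-from-logs oracle
  expect_equal(st$cs_coefficient,
               cs_from_draws(tidy(st), st$cor_threshold, st$prob_threshold))
  expect_true(st$cs_coefficient %in% c(0, st$drop_grid))
  # determinism
  st2 <- case_dropping_stability(surv, config = tiny_config(),
                                 drop_grid = c(0.1, 0.3, 0.5),
                                 n_boot = 150, seed = 12)
  expect_equal(st$draws, st2$draws)
})

test_that("threshold logic: proportions where all correlations clear 0.7 qualify", {
  draws <- dplyr::bind_rows(
    tibble::tibble(drop_proportion = 0.1, correlation = rep(1, 20)),
    tibble::tibble(drop_proportion = 0.3,
                   correlation = c(rep(0.9, 19), 0.2)),
    tibble::tibble(drop_proportion = 0.5,
                   correlation = c(rep(0.8, 10), rep(0.3, 10))))
  expect_equal(cs_from_draws(draws), 0.3)  # 19/20 = 0.95 still qualifies
  expect_equal(cs_from_draws(draws, prob_threshold = 0.96), 0.1)
  expect_equal(cs_from_draws(dplyr::filter(draws, drop_proportion == 0.5)), 0)
})

test_that("subsample correlations degrade with the drop proportion", {
  surv <- small_survey(n = 500, missing_rate = 0, seed = 66)
  st <- case_dropping_stability(surv, config = tiny_config(),
                                drop_grid = c(0.05, 0.45, 0.75),
                                n_boot = 90, seed = 4)
  med <- tidy(st) |>
    dplyr::group_by(.data$drop_proportion) |>
    dplyr::summarise(m = stats::median(.data$correlation, na.rm = TRUE))
  expect_gte(med$m[1], med$m[3] - 0.05)  # Monte-Carlo tolerance
})

test_that("subsamples below the node count are skipped with a warning", {
  surv <- small_survey(n = 10, missing_rate = 0, seed = 67)  # n = 40
  expect_warning(
    st <- case_dropping_stability(surv, config = tiny_config(),
                                  drop_grid = c(0.1, 0.75),
                                  n_boot = 20, seed = 5),
    "below node count")
  expect_false(0.75 %in% tidy(st)$drop_proportion)
  expect_true(0.1 %in% tidy(st)$drop_proportion)
})
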