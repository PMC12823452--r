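test_that("expected influence is the signed row sum of the weights", {
  net0 <- make_net(c("a", "b", "c"), rep("disability", 3))
  expect_equal(expected_influence(net0)$ei, c(0, 0, 0))

  net <- make_net(c("a", "b", "c"), rep("disability", 3),
                  tibble::tribble(~from, ~to, ~weight,
                                  "a", "b", 0.3,
                                  "a", "c", -0.1,
                                  "b", "c", 0.5))
  expect_equal(expected_influence(net)$ei, c(0.2, 0.8, 0.4))

  # invariant to node reordering
  perm <- c(3, 1, 2)
  net_p <- make_net(c("c", "a", "b"), rep("disability", 3),
                    tibble::tribble(~from, ~to, ~weight,
                                    "a", "b", 0.3,
                                    "a", "c", -0.1,
                                    "b", "c", 0.5))
  ei1 <- setNames(expected_influence(net)$ei, expected_influence(net)$node)
  ei2 <- setNames(expected_influence(net_p)$ei, expected_influence(net_p)$node)
  expect_equal(ei1[c("a", "b", "c")], ei2[c("a", "b", "c")])
})

test_that("bridge expected influence sums only cross-community edges", {
  nodes <- c("dep", "anx", "d1", "d2", "conf")
  comm <- c("wellbeing", "wellbeing", "disability", "disability", "confounder")
  # disability node with only within-community and confounder edges
  net1 <- make_net(nodes, comm,
                   tibble::tribble(~from, ~to, ~weight,
                                   "d1", "d2", 0.5,
                                   "d1", "conf", 0.2))
  bei1 <- bridge_expected_influence(net1)
  expect_equal(bei1$bei[bei1$node == "d1"], 0)

  # well-being node: edges to disability (0.2, -0.05) and confounder (0.4)
  net2 <- make_net(nodes, comm,
                   tibble::tribble(~from, ~to, ~weight,
                                   "dep", "d1", 0.2,
                                   "dep", "d2", -0.05,
                                   "dep", "conf", 0.4))
  bei2 <- bridge_expected_influence(net2)
  expect_equal(bei2$bei[bei2$node == "dep"], 0.15)

  # complete bipartite well-being/disability at weight w: every disability
  # node bridges both well-being nodes
  w <- 0.12
  net3 <- make_net(nodes, comm, tidyr::expand_grid(
    from = c("dep", "anx"), to = c("d1", "d2")) |>
      dplyr::mutate(weight = w))
  bei3 <- bridge_expected_influence(net3)
  expect_equal(bei3$bei[bei3$community == "disability"], c(2 * w, 2 * w))
})

test_that("confounders are outside the bridge definition", {
  net <- random_toy_net()
  cent <- centrality(net)
  expect_true(all(is.na(cent$bei[cent$community == "confounder"])))
  expect_true(all(!is.na(cent$bei[cent$community != "confounder"])))
  expect_false("c1" %in% bridge_expected_influence(net)$node)
  expect_error(bridge_expected_influence(net, from = "nope"), "community")
})

test_that("global strength is the absolute edge sum and is homogeneous", {
  net0 <- make_net(c("a", "b"), rep("disability", 2))
  expect_equal(global_strength(net0), 0)
  net <- make_net(c("a", "b", "c"), rep("disability", 3),
                  tibble::tribble(~from, ~to, ~weight,
                                  "a", "b", 0.3, "a", "c", -0.1, "b", "c", 0.5))
  expect_equal(global_strength(net), 0.9)
  expect_equal(global_strength(net$weights * 2.5), 2.5 * 0.9)
})

test_that("centralities agree with brute-force signed sums on random networks", {
  withr::with_seed(41, for (rep in 1:200) {
    net <- random_toy_net(p_dis = sample(2:5, 1), p_conf = sample(1:3, 1))
    W <- net$weights
    comm <- setNames(net$communities$community, net$communities$node)
    cent <- centrality(net)
    for (i in seq_along(net$node_names)) {
      v <- net$node_names[i]
      ei_brute <- sum(W[v, ])
      expect_equal(cent$ei[cent$node == v], ei_brute, tolerance = 1e-12)
      if (comm[v] != "confounder") {
        other <- if (comm[v] == "wellbeing") "disability" else "wellbeing"
        bei_brute <- sum(W[v, names(comm)[comm == other]])
        expect_equal(cent$bei[cent$node == v], bei_brute, tolerance = 1e-12)
        # identity: bei = ei - within-community and confounder edge sums
        own <- sum(W[v, comm == comm[v]]) + sum(W[v, comm == "confounder"])
        expect_equal(cent$bei[cent$node == v], cent$ei[cent$node == v] - own,
                     tolerance = 1e-12)
      }
    }
    # sum of EI double-counts every signed edge
    expect_equal(sum(cent$ei), 2 * sum(W[upper.tri(W)]), tolerance = 1e-10)
  })
})
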