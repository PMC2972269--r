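test_that("construction validates rule completeness and input names", {
  expect_error(build_network(c("A = B", "B = NOT A", "A = 1")), "duplicate")
  expect_error(build_network(c("A = B")), "B")
  expect_error(build_network(c("A = X AND A"), nodes = "A"), "X")
  expect_error(build_network(c("A = A PLUS 1")), "parse")
  net <- build_network(c("A = A"))
  expect_s3_class(net, "bnet")
  expect_identical(net$nodes, "A")
})

test_that("canonical node order is preserved independently of rule order", {
  net <- build_network(c("B = NOT A", "A = B"), nodes = c("A", "B"))
  expect_identical(net$nodes, c("A", "B"))
  expect_identical(sync_step(net, c(0, 0)), c(0L, 1L))
})

test_that("truth-table rows enumerate inputs most-significant-first", {
  # a single 1 in row 14 must fire exactly on input pattern 1101
  rules <- tibble::tibble(
    target = c("T", "a", "b", "c", "d"),
    inputs = list(c("a", "b", "c", "d"), "a", "b", "c", "d"),
    outputs = list(c(rep(0L, 13), 1L, 0L, 0L), 0:1, 0:1, 0:1, 0:1)
  )
  net <- build_network(rules)
  on <- sync_step(net, c(T = 0, a = 1, b = 1, c = 0, d = 1))[1]
  expect_identical(on, 1L)
  others <- decode_states(setdiff(0:15, 13), c("a", "b", "c", "d"))
  for (i in seq_len(nrow(others))) {
    expect_identical(sync_step(net, c(0, others[i, ]))[1], 0L)
  }
})

test_that("expression parsing produces the expected truth table", {
  net <- build_network(c("T = (A AND NOT B) OR (NOT A AND B)", "A = A", "B = B"))
  expect_identical(tidy(net)$outputs[1], "0110")
  expect_identical(tidy(net)$inputs[1], "A,B")
  net2 <- build_network(c("K = 1", "Z = 0"))
  expect_identical(tidy(net2)$outputs, c("1", "0"))
})

test_that("synchronous update matches hand-evaluated reference states", {
  netA <- build_scn_model("A")
  qc <- expected_states_A["QC", ]
  expect_identical(sync_step(netA, qc), unname(as.integer(qc)))
  zeros <- rep(0L, 9)
  expect_identical(sync_step(netA, zeros), c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  expect_error(sync_step(netA, rep(0L, 8)), "N = 9")
  # matrix form agrees with vector form
  S <- rbind(qc, zeros)
  expect_identical(unname(sync_step(netA, S)[1, ]), sync_step(netA, qc))
})

test_that("clamped nodes override their rule at every step", {
  netA <- build_scn_model("A")
  all_clamped <- netA
  for (n in netA$nodes) all_clamped <- clamp(all_clamped, n, 1)
  expect_identical(sync_step(all_clamped, rep(0L, 9)), rep(1L, 9))
  expect_error(clamp(netA, "XYZ", 0), "unknown node")
  expect_error(clamp(netA, "SHR", 2), "0 or 1")
  # clamping a node to its fixed-point value keeps the fixed point
  qc <- unname(expected_states_A["QC", ])
  cl <- clamp(netA, "WOX5", 1)
  expect_identical(sync_step(cl, qc), as.integer(qc))
  expect_identical(unclamp(cl)$clamps, integer(0))
})

test_that("the single self-copying node has two unit basins", {
  aset <- find_attractors(build_network("A = A"))
  expect_identical(n_attractors(aset), 2L)
  expect_identical(aset$periods, c(1L, 1L))
  expect_identical(aset$basin_counts, c(1, 1))
})

test_that("exhaustive basin counts always sum to 2^N", {
  for (seed in 1:5) {
    net <- random_network(7, 2, 0.5, seed = seed)
    aset <- find_attractors(net)
    expect_identical(sum(aset$basin_counts), 2^7)
    expect_false(any(duplicated(engine_attractor_keys(aset))))
  }
})

test_that("exhaustive attractors agree with the brute-force oracle", {
  grid <- expand.grid(N = c(5, 7), K = c(1, 3), seed = c(2, 9))
  for (i in seq_len(nrow(grid))) {
    net <- random_network(grid$N[i], grid$K[i], 0.5, seed = grid$seed[i])
    expect_identical(engine_attractor_keys(find_attractors(net)),
                     oracle_attractor_keys(funs_from_rules(net)))
  }
  # clamped dynamics too
  net <- random_network(6, 2, 0.5, seed = 4)
  cl <- clamp(net, net$nodes[1], 1)
  expect_identical(engine_attractor_keys(find_attractors(cl)),
                   oracle_attractor_keys(funs_from_rules(net),
                                         clamps = c(n1 = 1)))
  # and the reference model A against hand-written rules
  expect_identical(engine_attractor_keys(find_attractors(build_scn_model("A"))),
                   oracle_attractor_keys(scn_A_funs))
})

test_that("sampled attractor sets are subsets of the exhaustive set", {
  for (seed in c(3, 8)) {
    net <- random_network(8, 2, 0.5, seed = seed)
    ex <- engine_attractor_keys(find_attractors(net))
    sm <- find_attractors(net, mode = "sampled", n_samples = 400, seed = 11)
    expect_true(all(engine_attractor_keys(sm) %in% ex))
    expect_identical(sum(sm$basin_counts), 400)
  }
  expect_error(find_attractors(build_scn_model("A"), mode = "sampled"), "seed")
})

test_that("cyclic attractors of any period are detected in both modes", {
  net <- build_network(c("A = B", "B = NOT A"))
  ex <- find_attractors(net)
  expect_identical(ex$periods, 4L)
  expect_identical(ex$basin_counts, 4)
  sm <- find_attractors(net, mode = "sampled", n_samples = 50, seed = 1)
  expect_identical(engine_attractor_keys(sm), engine_attractor_keys(ex))
  traj <- simulate_trajectory(net, c(0, 0))
  expect_identical(traj$period, 4L)
  expect_identical(traj$transient_length, 0L)
})

test_that("identical model and state always give identical trajectories", {
  net <- random_network(9, 2, 0.5, seed = 21)
  s <- decode_states(137, net$nodes)[1, ]
  t1 <- simulate_trajectory(net, s)
  t2 <- simulate_trajectory(net, s)
  expect_identical(t1$states, t2$states)
})

test_that("exhaustive requests above the cap advise sampled mode", {
  net <- random_network(12, 2, 0.5, seed = 1)
  expect_error(find_attractors(net, exhaustive_cap = 10), "sampled")
  expect_error(find_attractors(net), NA)
})

test_that("basin membership reports the initial-state assignment", {
  net <- build_network(c("A = A", "B = A"))
  aset <- find_attractors(net)
  bm <- basin_membership(aset)
  expect_identical(nrow(bm), 4L)
  # A = 0 states end in the all-zero attractor regardless of B
  zero_att <- bm$attractor[bm$A == 0]
  expect_identical(length(unique(zero_att)), 1L)
})
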