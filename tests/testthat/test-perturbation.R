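test_that("loss of SHR leaves only the columella/epidermis configuration", {
  for (v in scn_variants()) {
    aset <- simulate_mutant(build_scn_model(v), "SHR", "loss")
    expect_identical(n_attractors(aset), 1L, info = v)
    expected <- expected_states_for(v)["CEpI", ]
    expect_identical(drop(aset$attractors[[1]]), expected, info = v)
  }
})

test_that("loss of SCR in B' keeps CEpI and both vascular states only", {
  net <- build_scn_model("B_prime")
  aset <- simulate_mutant(net, "SCR", "loss",
                          profiles = scn_reference_profiles("B_prime"))
  keys <- engine_attractor_keys(aset)
  expected <- expected_states_for("B_prime")
  expect_identical(keys,
                   unname(state_keys(expected[c("CEpI", "vascular0", "vascular1"), ])))
  # no JKD activity can survive without SCR
  expect_true(all(tidy(aset)$JKD == 0))
})

test_that("jkd loss keeps the CEI-like state only where SCR escapes JKD control", {
  cei_like <- function(v) {
    aset <- simulate_mutant(build_scn_model(v), "JKD", "loss",
                            profiles = scn_reference_profiles(v))
    any(aset$labels == "CEI" & attr(aset, "label_distance") == 0, na.rm = TRUE)
  }
  expect_false(cei_like("A"))
  expect_false(cei_like("B"))
  expect_true(cei_like("A_prime"))
  expect_true(cei_like("B_prime"))
  # in A the QC-marking WOX5 stays expressed even though CEI is lost
  a <- simulate_mutant(build_scn_model("A"), "JKD", "loss",
                       profiles = scn_reference_profiles("A"))
  expect_true(any(tidy(a)$WOX5 == 1))
})

test_that("mgp loss is silent in the B variants but collapses CEI into QC in A", {
  for (v in c("B", "B_prime")) {
    net <- build_scn_model(v)
    wt <- find_attractors(net)
    mut <- simulate_mutant(net, "MGP", "loss")
    expect_true(same_attractors(wt, mut, exclude = "MGP"), info = v)
  }
  for (v in c("A", "A_prime")) {
    net <- build_scn_model(v)
    wt <- label_attractors(find_attractors(net), scn_reference_profiles(v))
    mut <- label_attractors(find_attractors(clamp(net, "MGP", 0)),
                            scn_reference_profiles(v), exclude = "MGP")
    expect_false("CEI" %in% mut$labels, info = v)
    # the initial conditions that led to CEI now lead to the QC attractor
    cei_wt <- which(wt$labels == "CEI")
    qc_mut <- which(mut$labels == "QC")
    shifted <- mut$assignment[wt$assignment == cei_wt]
    expect_true(all(shifted == qc_mut), info = v)
  }
})

test_that("remaining B' loss-of-function rows match their described outcomes", {
  net <- build_scn_model("B_prime")
  prof <- scn_reference_profiles("B_prime")
  wt <- find_attractors(net)
  run <- function(node) simulate_mutant(net, node, "loss", profiles = prof)

  wox5 <- run("WOX5")   # QC configuration lost, CEI intact
  expect_false("QC" %in% wox5$labels)
  expect_true("CEI" %in% wox5$labels)

  plt <- run("PLT")     # pure output: everything else unchanged
  expect_true(same_attractors(wt, plt, exclude = "PLT"))

  iaa <- run("AuxIAA")  # already off in every attractor
  expect_true(same_attractors(wt, iaa, exclude = "AuxIAA"))

  arf <- run("ARF")     # WOX5 needs ARF: QC lost, WOX5 silent everywhere
  expect_true(all(tidy(arf)$WOX5 == 0))
  expect_false("QC" %in% arf$labels)

  aux <- run("auxin")   # signalling collapses: no ARF, PLT or WOX5 activity
  td <- tidy(aux)
  expect_true(all(td$ARF == 0) && all(td$PLT == 0) && all(td$AuxIAA == 1))
  expect_true(all(td$WOX5 == 0))
})

test_that("gain-of-function clamps apply from the initial state onwards", {
  net <- build_scn_model("B_prime")
  gain <- simulate_mutant(net, "WOX5", "gain")
  expect_true(all(tidy(gain)$WOX5 == 1))
  expect_true(all(tidy(gain)$MGP == 0))  # WOX5 represses MGP everywhere
  expect_error(simulate_mutant(net, "nope", "loss"), "unknown node")
})

test_that("the rule-flip scan enumerates every output bit once", {
  arities <- list(A = 69L, A_prime = 69L, B = 85L, B_prime = 85L)
  for (v in c("A", "B_prime")) {
    net <- build_scn_model(v)
    rob <- rule_flip_scan(net)
    expect_identical(rob$total_flips,
                     sum(vapply(net$rules, function(r) length(r$outputs), integer(1))))
    expect_identical(rob$total_flips, arities[[v]])
    expect_identical(rob$unchanged + rob$changed, rob$total_flips)
    expect_true(rob$fraction_unchanged > 0 && rob$fraction_unchanged < 1)
    # flipping the constant auxin source row must change the attractor set
    expect_false(tidy(rob)$unchanged[tidy(rob)$node == "auxin"])
  }
})

test_that("the null perturbation leaves the attractor set unchanged", {
  net <- build_scn_model("A")
  wt1 <- engine_attractor_keys(find_attractors(net))
  wt2 <- engine_attractor_keys(find_attractors(net))
  expect_identical(wt1, wt2)
  # a double flip restores the wild type exactly
  alt <- net
  alt$rules$SCR$outputs[3] <- 1L - alt$rules$SCR$outputs[3]
  alt$rules$SCR$outputs[3] <- 1L - alt$rules$SCR$outputs[3]
  expect_identical(engine_attractor_keys(find_attractors(alt)), wt1)
})

test_that("flipping SCR line 14 of model A reproduces the A' attractors", {
  netA <- build_scn_model("A")
  flipped <- netA
  flipped$rules$SCR$outputs[14] <- 1L - flipped$rules$SCR$outputs[14]
  flipped$rules$SCR$expr <- NULL
  expect_identical(tidy(flipped)$outputs, tidy(build_scn_model("A_prime"))$outputs)
  expect_identical(engine_attractor_keys(find_attractors(flipped)),
                   engine_attractor_keys(find_attractors(build_scn_model("A_prime"))))
})

test_that("the Derrida map is anchored at zero and preserved by copy networks", {
  net <- build_scn_model("A")
  d0 <- derrida_map(net, n_pairs = 200, seed = 3, distances = 0)
  expect_identical(tidy(d0)$h_t1, 0)
  ident <- build_network(paste0("n", 1:6, " = n", 1:6))
  di <- derrida_map(ident, n_pairs = 500, seed = 5)
  expect_equal(tidy(di)$h_t1, tidy(di)$h_t, tolerance = 1e-12)
  expect_error(derrida_map(net, n_pairs = 100), "seed")
})

test_that("critical NK networks keep small perturbations near the identity line", {
  net <- random_network(30, 2, 0.5, seed = 17)
  d <- derrida_map(net, n_pairs = 2000, seed = 18, distances = 1:3)
  pts <- tidy(d)
  # slope at the origin ~ 2 K p (1-p) = 1 for K = 2, p = 0.5
  expect_equal(pts$h_t1 / pts$h_t, rep(1, 3), tolerance = 0.2)
})
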