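test_that("the meta-network couples four B' copies with the stated clamps", {
  meta <- build_meta_grn("B_prime")
  expect_length(meta$nodes, 40)
  expect_identical(meta$clamps,
                   c(SHR_V = 1L, SCR_V = 0L, auxin_V = 1L, auxin_C = 1L))
  expect_error(build_meta_grn("A"), "B_prime")
  bad <- scn_mobility_spec()
  bad$mobile <- c("SHR", "auxin")
  expect_error(build_meta_grn("B_prime", bad), "malformed")
})

test_that("mobility terms follow the movement semantics of each component", {
  meta <- build_meta_grn("B_prime")
  td <- tidy(meta)
  rule_inputs <- function(target) {
    strsplit(td$inputs[td$target == target], ",", fixed = TRUE)[[1]]
  }
  # SHR enters the columella initials only from a QC without SCR
  expect_setequal(rule_inputs("SHR_E"), c("SHR_Q", "SCR_Q"))
  # CLEX outside the QC is activated by WOX5 from any cell; not in the QC
  expect_true(all(paste0("WOX5_", c("V", "C", "Q", "E")) %in% rule_inputs("CLEX_C")))
  expect_identical(td$inputs[td$target == "CLEX_Q"], "")
  expect_identical(td$outputs[td$target == "CLEX_Q"], "0")
  # the QC's WOX5 escapes the long-range CLEX inhibition
  expect_false(any(grepl("CLEX", rule_inputs("WOX5_Q"))))
  expect_true(any(grepl("CLEX", rule_inputs("WOX5_C"))))
  # immobile components never read another cell's state; the only cross-cell
  # read of a non-mobile node is SCR gating SHR export from its source cell
  mobile <- scn_mobility_spec()$mobile
  for (i in seq_len(nrow(td))) {
    target_base <- sub("_[VCQE]$", "", td$target[i])
    cell <- sub("^.*_", "", td$target[i])
    for (inp in strsplit(td$inputs[i], ",", fixed = TRUE)[[1]]) {
      base <- sub("_[VCQE]$", "", inp)
      if (sub("^.*_", "", inp) != cell) {
        ok <- base %in% mobile || (target_base == "SHR" && base == "SCR")
        expect_true(ok, label = paste(td$target[i], "reads", inp))
      }
    }
  }
})

test_that("every sampled start converges to the published niche arrangement", {
  meta <- build_meta_grn("B_prime")
  gl <- find_global_attractors(meta, n_samples = 2000, seed = 19)
  expect_identical(n_attractors(gl), 1L)
  expect_identical(gl$periods, 1L)
  att <- drop(gl$attractors[[1]])
  pat <- spatial_pattern(meta, att)
  expect_identical(pat$label, c("vascular", "CEI", "QC", "CEpI"))
  # WOX5 is expressed exclusively in the QC
  wox5 <- att[grep("^WOX5_", names(att))]
  expect_identical(unname(wox5), c(0L, 0L, 1L, 0L))
  # per-cell projections equal the single-cell reference rows
  expect_identical(unname(cell_projection(meta, att, "Q")),
                   unname(as.integer(expected_states_B["QC", ])))
  expect_identical(unname(cell_projection(meta, att, "C")),
                   unname(as.integer(expected_states_B["CEI", ])))
  expect_identical(unname(cell_projection(meta, att, "E")),
                   unname(as.integer(expected_states_B["CEpI", ])))
  # a single sample returns that trajectory's attractor only
  one <- find_global_attractors(meta, n_samples = 1, seed = 4)
  expect_identical(n_attractors(one), 1L)
})

test_that("without the SCR convention the all-zero start never gains SCR", {
  meta <- build_meta_grn("B_prime")
  run <- run_spatial(meta, rep(0L, 40), scr_convention = "off")
  att <- drop(run$attractor)
  expect_true(all(att[grep("^SCR_", names(att))] == 0L))
  # with the convention the same start patterns correctly
  run_on <- run_spatial(meta, rep(0L, 40), scr_convention = "on")
  expect_identical(run_on$pattern$label, c("vascular", "CEI", "QC", "CEpI"))
  # forced steps are visible at t = 0 and t = 1
  expect_true(all(run_on$trajectory[1:2, c("SCR_C", "SCR_Q", "SCR_E")] == 1L))
  expect_identical(unname(run_on$trajectory[1:2, "SCR_V"]), c(0L, 0L))
})

test_that("scr loss removes QC and CEI and lets SHR invade the columella initials", {
  meta <- build_meta_grn("B_prime")
  sm <- simulate_spatial_mutant(meta, "SCR", "loss", n_samples = 2000, seed = 23)
  expect_false(any(c("QC", "CEI") %in% unlist(sm$patterns[c("V", "C", "Q", "E")])))
  for (aset in sm$runs) {
    for (a in aset$attractors) {
      expect_identical(unname(drop(a)[["SHR_E"]]), 1L)
    }
  }
})

test_that("SHR gain yields both a CEI-like and a CEpI-plus-SHR columella outcome", {
  meta <- build_meta_grn("B_prime")
  sm <- simulate_spatial_mutant(meta, "SHR", "gain", n_samples = 2000, seed = 29)
  mut <- sm$model
  cei <- expected_states_B["CEI", ]
  cepi_shr <- expected_states_B["CEpI", ]
  cepi_shr["SHR"] <- 1
  seen_cei <- FALSE
  seen_cepi_shr <- FALSE
  for (aset in sm$runs) {
    for (a in aset$attractors) {
      proj <- cell_projection(mut, drop(a), "E")
      if (identical(unname(proj), unname(as.integer(cei)))) seen_cei <- TRUE
      if (identical(unname(proj[names(proj) != "CLEX"]),
                    unname(as.integer(cepi_shr[names(cepi_shr) != "CLEX"])))) {
        seen_cepi_shr <- TRUE
      }
    }
  }
  expect_true(seen_cei)
  expect_true(seen_cepi_shr)
})

test_that("mgp loss leaves the wild-type spatial pattern untouched", {
  meta <- build_meta_grn("B_prime")
  wt <- find_global_attractors(meta, n_samples = 2000, seed = 37)
  sm <- simulate_spatial_mutant(meta, "MGP", "loss", n_samples = 2000, seed = 37,
                                conventions = "on")
  mut_set <- sm$runs[["on"]]
  expect_identical(n_attractors(mut_set), 1L)
  mgp_vars <- paste0("MGP_", c("V", "C", "Q", "E"))
  keep <- setdiff(meta$nodes, mgp_vars)
  expect_identical(drop(mut_set$attractors[[1]])[keep],
                   drop(wt$attractors[[1]])[keep])
  expect_error(simulate_spatial_mutant(meta, "XYZ", "loss", seed = 1),
               "unknown")
})

test_that("the continuous spatial system reproduces the discrete arrangement", {
  meta <- build_meta_grn("B_prime")
  res <- spatial_continuous_check(meta, n_starts = 3, seed = 41)
  expect_true(all(res$matches_discrete))
})
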