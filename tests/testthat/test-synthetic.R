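test_that("scenario constructor validates its stated world", {
  scn <- simulation_scenario()
  expect_s3_class(scn, "sim_scenario")
  expect_equal(scn$G_true, 0.4 * scn$P_true)
  expect_equal(unique(ne_over_t(scn$params, "mean")), 1)
  expect_equal(length(scn$phy$tip.label), 8L)
  expect_error(simulation_scenario(P_true = matrix(c(1, 2, 2, 1), 2),
                                   p = 2), "PSD")
  expect_error(simulation_scenario(selected_branch = "nope",
                                   beta_true = rep(1, 6)), "not a node")
  expect_error(simulation_scenario(selected_branch = "t1"), "beta_true")
  expect_error(simulation_scenario(shift_scale = -1), "shift_scale")
})

test_that("drift means: zero-variance limit and increment variance", {
  # Ne -> infinity: every node collapses onto the root mean
  # (per-branch sd = sqrt(t/Ne) = 1e-5 here)
  scn <- simulation_scenario(Ne = 1e14, seed = 2)
  m <- simulate_drift_means(scn)
  expect_lt(max(abs(m)), 1e-3)

  # single trait, two-tip tree, t/Ne = 4: increment variance 4
  phy <- fix_two_tip()
  scn1 <- simulation_scenario(phy = phy, p = 1,
                              P_true = matrix(1 / 0.4), h2 = 0.4,
                              Ne = 2500, divergence_time = 250000,
                              generation_length = 25, seed = 3)
  expect_equal(unique(ne_over_t(scn1$params, "mean")), 0.25)  # G = 1
  reps <- vapply(1:10000, function(r)
    simulate_drift_means(scn1, seed = r)["A", 1], numeric(1))
  expect_equal(stats::var(reps), 4, tolerance = 0.05 * 4)

  # selected branch with diagonal G and beta = e1 shifts only trait 1
  scn_e1 <- simulation_scenario(p = 3, P_true = diag(3), h2 = 0.4,
                                Ne = 1e12,
                                selected_branch = "t1",
                                beta_true = c(1, 0, 0),
                                shift_scale = 5, seed = 4)
  me <- simulate_drift_means(scn_e1)
  shift <- me["t1", ] - me["node3", ]   # node3 = parent of the t1 cherry
  expect_equal(unname(shift[1]), 5 * 0.4, tolerance = 1e-3)
  expect_lt(max(abs(shift[2:3])), 1e-3)
})

test_that("specimen simulation is seeded and sex-structured", {
  scn <- simulation_scenario(seed = 10, n_per_taxon = 30)
  m <- simulate_drift_means(scn)
  t1 <- simulate_specimens(scn, m, seed = 77)
  t2 <- simulate_specimens(scn, m, seed = 77)
  expect_identical(t1, t2)
  expect_false(identical(simulate_specimens(scn, m, seed = 78), t1))
  expect_equal(nrow(t1), 8 * 30)
  expect_equal(unname(table(t1$sex)), c(120, 120), ignore_attr = TRUE)
  expect_error(simulate_specimens(simulation_scenario(n_per_taxon = 1),
                                  m), ">= 2")

  # a large sex effect inflates raw covariance but not the corrected W
  sx <- c(5, rep(0, 5))
  scn_sx <- simulation_scenario(seed = 11, n_per_taxon = 60,
                                sex_effect = sx)
  msx <- simulate_drift_means(scn_sx)
  tsx <- simulate_specimens(scn_sx, msx)
  raw_var <- stats::var(trait_matrix(tsx)[, 1])
  w <- pooled_within_cov(residualize(tsx))
  expect_gt(raw_var, 5)            # ~ 1 + (5/2)^2 pooled-sex inflation
  expect_equal(unname(w$W[1, 1]), 1, tolerance = 0.25)

  # with no sex effect, pooled-sex and corrected W agree
  scn0 <- simulation_scenario(seed = 12, n_per_taxon = 60)
  t0 <- simulate_specimens(scn0, simulate_drift_means(scn0))
  w0 <- pooled_within_cov(residualize(t0))
  z0 <- trait_matrix(t0)
  taxon_only <- z0 - rowsum(z0, t0$taxon)[t0$taxon, ] /
    as.vector(table(t0$taxon))[match(t0$taxon, names(table(t0$taxon)))]
  expect_equal(unname(diag(w0$W)),
               unname(colSums(taxon_only^2) / (nrow(z0) - 8)),
               tolerance = 0.1)
})

test_that("null calibration tracks nominal levels with truth supplied", {
  scn <- simulation_scenario(seed = 20)
  nc <- null_calibration_experiment(scn, n_reps = 300)
  # alpha1 = 0.05 per tail: 0.10 nominal two-sided
  expect_gt(nc$overall[["reject_alpha1"]], 0.05)
  expect_lt(nc$overall[["reject_alpha1"]], 0.15)
  # alpha2 = 0.001 per tail: rare rejections
  expect_lt(nc$overall[["reject_alpha2"]], 0.01)
  expect_equal(dim(nc$ggd), c(300L, 14L))
  expect_error(null_calibration_experiment(strong_scenario()),
               "pure-drift")
})

test_that("estimated-W calibration runs and its inflation is reported", {
  scn <- simulation_scenario(seed = 23, n_per_taxon = 25)
  nc <- suppressWarnings(
    null_calibration_experiment(scn, n_reps = 30, estimate = TRUE))
  expect_equal(dim(nc$ggd), c(30L, 14L))
  expect_true(is.finite(nc$overall[["reject_alpha1"]]))
})

test_that("wrong branches are almost never flagged very_fast under drift", {
  scn <- simulation_scenario(seed = 24)
  nc <- null_calibration_experiment(scn, n_reps = 300)
  regime <- classify_rate(nc$ggd, df = scn$p)
  n_vf_up <- sum(regime == "very_fast")
  # one-sided binomial bound at the 0.999 level for rate alpha2 = 0.001
  expect_lte(n_vf_up, qbinom(0.999, length(regime), 0.001))
})

test_that("recovery power is non-decreasing in the shift scale", {
  grid <- c(0, 0.5, 1, 2)
  n_reps <- 80
  pw <- vapply(grid, function(cc) {
    scn <- simulation_scenario(selected_branch = "t1",
                               beta_true = c(2, -1.5, 1, 0, 0, 0),
                               shift_scale = cc, seed = 30)
    recovery_experiment(scn, n_reps = n_reps)$summary[["flag_rate"]]
  }, numeric(1))
  se <- sqrt(pmax(pw * (1 - pw), 0.25 / n_reps) / n_reps)
  # monotone up to twice the Monte-Carlo standard error
  expect_true(all(diff(pw) >= -2 * (se[-1] + se[-length(se)])))
  # and clearly increasing from the null to the strongest setting
  expect_gt(pw[4], pw[1])
})

test_that("write_scenario emits a loadable, truthful bundle", {
  dir <- withr::local_tempdir()
  scn <- strong_scenario(seed = 41)
  paths <- write_scenario(scn, dir)
  expect_true(all(file.exists(paths)))
  phy <- read_phylogeny(paths[["tree"]])
  expect_equal(sort(phy$tip.label), sort(scn$phy$tip.label))
  tt <- read_trait_table(paths[["traits"]])
  expect_equal(nrow(tt), 8 * scn$n_per_taxon)
  expect_true(validate_traits_vs_tree(tt, phy))
  params <- read_branch_params(paths[["params"]])
  expect_equal(sort(params$node_id),
               sort(unname(ggdrift:::internal_node_ids(phy))))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$selected_branch, "t1")
  expect_equal(truth$beta_true, c(2, -1.5, 1, 0, 0, 0))
  # trait CSV is centred on the truth's tip means
  tm <- tip_means(tt)
  nm <- truth$node_means
  t3 <- unlist(nm[nm$node == "t3", -1])
  expect_lt(max(abs(tm["t3", ] - t3)), 0.5)
})
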