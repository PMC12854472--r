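test_that("selection_gradient solves W beta = dz, descendant minus ancestor", {
  expect_equal(selection_gradient(c(0, 0), c(1, -2), diag(2)), c(1, -2))
  W <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(selection_gradient(c(0, 0), c(1, 1), solve(W)),
               c(2 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(selection_gradient(c(3, 4), c(3, 4), solve(W)), c(0, 0))
  expect_error(selection_gradient(c(1, 2), c(1, 2, 3), diag(2)), "length")

  # equivariance: doubling dz doubles beta; W -> h2 W multiplies by 1/h2
  set.seed(3)
  dz <- rnorm(4); Wr <- crossprod(matrix(rnorm(16), 4))
  b <- selection_gradient(rep(0, 4), dz, solve(Wr))
  expect_equal(selection_gradient(rep(0, 4), 2 * dz, solve(Wr)), 2 * b)
  expect_equal(selection_gradient(rep(0, 4), dz, solve(0.4 * Wr)),
               b / 0.4, tolerance = 1e-10)
})

test_that("bootstrap CIs are seeded, degenerate on constant data", {
  tt <- make_traits(matrix(rep(c(1, 2), each = 6), 6, 2),
                    rep("A", 6), rep(c("F", "M"), 3))
  # all specimens identical: zero-width CI at beta
  bs <- bootstrap_gradient_ci(tt, "A", c(0, 0), diag(2), B = 50, seed = 4)
  expect_equal(unname(bs$ci[, "lower"]), unname(bs$beta))
  expect_equal(unname(bs$ci[, "upper"]), unname(bs$beta))
  expect_equal(unname(bs$beta), c(1, 2))

  set.seed(90)
  tt2 <- make_traits(matrix(rnorm(40), 20, 2), rep("A", 20),
                     rep(c("F", "M"), 10))
  b1 <- bootstrap_gradient_ci(tt2, "A", c(0, 0), diag(2), B = 200, seed = 7)
  b2 <- bootstrap_gradient_ci(tt2, "A", c(0, 0), diag(2), B = 200, seed = 7)
  expect_identical(b1$ci, b2$ci)
  b3 <- bootstrap_gradient_ci(tt2, "A", c(0, 0), diag(2), B = 200, seed = 8)
  expect_false(identical(b3$ci, b1$ci))

  # the global RNG stream is left untouched
  set.seed(123); before <- .Random.seed
  invisible(bootstrap_gradient_ci(tt2, "A", c(0, 0), diag(2),
                                  B = 20, seed = 5))
  expect_identical(.Random.seed, before)

  one <- make_traits(matrix(1, 1, 2), "A", "F")
  expect_error(bootstrap_gradient_ci(one, "A", c(0, 0), diag(2)), ">= 2")
  expect_error(bootstrap_gradient_ci(tt2, "A", c(0, 0), diag(2), B = 0),
               "B must be")
})

test_that("response_pct back-transforms logged means", {
  expect_equal(response_pct(1.3, 1.3), 0)
  expect_equal(response_pct(2, 2 + log(1.1)), 10, tolerance = 1e-10)
  # sign follows the logged difference on the geometric scale
  set.seed(6)
  a <- rnorm(30); d <- rnorm(30)
  expect_equal(sign(response_pct(a, d)), sign(d - a))
  expect_equal(response_pct(2, 3, scale = "logged"), 50)
  expect_error(response_pct(0, 1, scale = "logged"), "undefined")
  expect_error(response_pct(NA_real_, 1), "non-finite")
})

test_that("classify_selection matches the hand truth table", {
  # 3x3 grid: CI position x response sign
  grid <- expand.grid(ci = c("neg", "zero", "pos"),
                      resp = c(-1, 0, 1), stringsAsFactors = FALSE)
  ci_lo <- c(neg = -0.9, zero = -0.3, pos = 0.2)
  ci_hi <- c(neg = -0.2, zero = 0.4, pos = 0.9)
  beta <- c(neg = -0.5, zero = 0.1, pos = 0.5)
  got <- classify_selection(beta[grid$ci], ci_lo[grid$ci],
                            ci_hi[grid$ci], grid$resp)
  want <- character(9)
  for (k in seq_len(9)) {
    want[k] <- if (grid$ci[k] == "zero") "none"
    else if (grid$ci[k] == "pos" && grid$resp[k] > 0) "direct_increase"
    else if (grid$ci[k] == "neg" && grid$resp[k] < 0) "direct_decrease"
    else "indirect"
  }
  expect_equal(got, want)
  # named cases: significant-negative CI with positive response is the
  # covariance-driven (indirect) pattern; zero-spanning CI is none
  expect_equal(classify_selection(-0.5, -0.9, -0.2, 1), "indirect")
  expect_equal(classify_selection(0.1, -0.3, 0.4, 5), "none")
  expect_equal(classify_selection(0.5, 0.2, 0.9, 3), "direct_increase")
  expect_error(classify_selection(0, 1, -1, 0), "malformed")
})

test_that("branch_selection assembles a per-trait result table", {
  scn <- strong_scenario(seed = 55)
  m <- simulate_drift_means(scn)
  tt <- simulate_specimens(scn, m)
  anc <- estimate_ancestral_states(scn$phy, tip_means(tt))
  wl <- branch_winv(scn$phy, tt, ggd_config(pooling = "all"))
  sel <- branch_selection(tt, "t1", anc$estimate["node3", ],
                          wl[["node3"]]$inv, B = 200, seed = 9)
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$trait, trait_names(tt))
  expect_equal(sel$significant, sel$ci_lower > 0 | sel$ci_upper < 0)
  expect_true(all(sel$classification[!sel$significant] == "none"))
  # direct_* implies matching signs
  dir_up <- sel$classification == "direct_increase"
  expect_true(all(sel$beta[dir_up] > 0 & sel$response_pct[dir_up] > 0))
})

test_that("selection_report groups, sorts and summarizes", {
  res <- data.frame(
    trait = paste0("t", 1:9),
    beta = c(3, 2, 1, -1, -2, 0.5, -0.5, 4, -3),
    ci_lower = c(2, 1, -1, -2, -3, 0.1, -1.5, 3, -4),
    ci_upper = c(4, 3, 2, 0.5, -1, 0.9, 0.5, 5, -2),
    response_pct = c(5, -1, 2, -2, -4, 3, 1, 6, 2),
    stringsAsFactors = FALSE)
  res$significant <- res$ci_lower > 0 | res$ci_upper < 0
  res$classification <- classify_selection(res$beta, res$ci_lower,
                                           res$ci_upper, res$response_pct)
  rep1 <- selection_report(res, list(symphyseal = paste0("t", 1:9)))
  summ <- attr(rep1, "summary")
  n_direct <- sum(startsWith(res$classification, "direct"))
  expect_equal(summ$line[summ$group == "symphyseal"],
               sprintf("%d/9 direct", n_direct))
  # sorted descending beta within group
  expect_equal(rep1$beta, sort(res$beta, decreasing = TRUE))
  # empty designation omitted; ungrouped traits collected
  rep2 <- selection_report(res, list(a = character(0),
                                     b = c("t1", "t2")))
  expect_false("a" %in% rep2$group)
  expect_true(all(c("b", "ungrouped") %in% rep2$group))
  # all-zero gradients with zero-spanning CIs: everything none
  res0 <- res
  res0$beta <- 0; res0$ci_lower <- -1; res0$ci_upper <- 1
  res0$classification <- classify_selection(res0$beta, res0$ci_lower,
                                            res0$ci_upper,
                                            res0$response_pct)
  expect_true(all(res0$classification == "none"))
})
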