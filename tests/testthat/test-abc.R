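# build a toy reference table from raw summary draws
toy_ref <- function(n, scen = NULL, mean = 0, sd = 1) {
  S <- matrix(rnorm(n * 15, mean, sd), n, 15,
              dimnames = list(NULL, summary_names()))
  cbind(data.frame(scenario = if (is.null(scen))
    sample(1:2, n, TRUE) else scen,
    N1 = runif(n, 10, 15000), N2 = runif(n, 10, 10000),
    N3 = runif(n, 10, 10000), t_recent = runif(n, 10, 500),
    t_deep = runif(n, 500, 15000), ra = runif(n)),
    as.data.frame(S))
}

test_that("rejection keeps the closest tolerance fraction, ties by row order", {
  set.seed(121)
  ref <- toy_ref(200)
  obs <- setNames(as.numeric(ref[17, summary_names()]), summary_names())
  rej <- abc_rejection(ref, obs, tolerance = 0.01)
  expect_equal(length(rej$indices), 2)
  expect_true(17 %in% rej$indices)
  expect_equal(min(rej$distances), 0)
})

test_that("rejection equals a brute-force sort on random instances", {
  set.seed(122)
  for (k in 1:100) {
    n <- sample(50:200, 1)
    ref <- toy_ref(n)
    obs <- setNames(rnorm(15), summary_names())
    tol <- runif(1, 0.02, 0.3)
    rej <- abc_rejection(ref, obs, tolerance = tol)
    # independent: standardize and sort all distances
    S <- as.matrix(ref[, summary_names()])
    Z <- sweep(S, 2, apply(S, 2, sd), "/")
    zo <- obs / apply(S, 2, sd)
    d <- sqrt(colSums((t(Z) - zo)^2))
    expect_equal(sort(rej$indices), sort(order(d)[seq_len(ceiling(tol * n))]))
  }
})

test_that("zero-variance summary columns are dropped with a warning", {
  set.seed(123)
  ref <- toy_ref(100)
  ref$m_1 <- 1  # constant column
  obs <- setNames(rnorm(15), summary_names())
  expect_warning(rej <- abc_rejection(ref, obs, 0.1), "zero-variance")
  expect_equal(rej$dropped_columns, "m_1")
  expect_equal(length(rej$indices), 10)
})

test_that("scenario posteriors are degenerate when one scenario survives", {
  set.seed(124)
  ref <- toy_ref(100, scen = 2)
  obs <- setNames(rnorm(15), summary_names())
  rej <- abc_rejection(ref, obs, 0.5)
  expect_warning(sp <- scenario_posterior(rej$accepted, rej$distances, obs),
                 "degenerate")
  expect_equal(sp$posterior[sp$scenario == 2], 1)
  expect_equal(sum(sp$posterior), 1)
})

test_that("labels independent of the summaries give posterior ~0.5", {
  set.seed(125)
  p2 <- replicate(10, {
    ref <- toy_ref(1500)
    obs <- setNames(rnorm(15, 0, 0.3), summary_names())
    rej <- abc_rejection(ref, obs, 0.1)
    sp <- scenario_posterior(rej$accepted, rej$distances, obs)
    sp$posterior[sp$scenario == 2]
  })
  expect_equal(mean(p2), 0.5, tolerance = 0.05)
  expect_true(all(abs(p2 - 0.5) < 0.25))
})

test_that("scenario posteriors always sum to 1 with ordered intervals", {
  set.seed(126)
  ref <- toy_ref(800)
  ref$na_1 <- ref$na_1 + 0.8 * (ref$scenario == 2)  # informative summary
  obs <- setNames(rnorm(15), summary_names())
  rej <- abc_rejection(ref, obs, 0.2)
  sp <- scenario_posterior(rej$accepted, rej$distances, obs)
  expect_equal(sum(sp$posterior), 1, tolerance = 1e-9)
  expect_true(all(sp$lower <= sp$posterior & sp$posterior <= sp$upper))
})

test_that("a parameter independent of the summaries keeps its prior", {
  set.seed(127)
  ref <- toy_ref(4000, scen = 2)
  obs <- setNames(rnorm(15, 0, 0.2), summary_names())
  rej <- abc_rejection(ref, obs, 0.25)
  pp <- parameter_posterior(rej$accepted, rej$distances, obs,
                            parameters = "t_recent")
  # adjusted posterior should still look like Uniform(10, 500)
  ks <- suppressWarnings(stats::ks.test(pp$sample[, "t_recent"],
                                        "punif", 10, 500))
  expect_lt(unname(ks$statistic), 0.08)
  expect_equal(pp$summary$mean, 255, tolerance = 0.1)
})

test_that("parameter posteriors stay inside the prior support", {
  set.seed(128)
  ref <- toy_ref(1000, scen = 2)
  # make t_recent strongly correlated with a summary so adjustment acts
  ref$he_1 <- (ref$t_recent - 255) / 150 + rnorm(1000, 0, 0.2)
  obs <- setNames(c(rnorm(3), 1.2, rnorm(11)), summary_names())
  rej <- abc_rejection(ref, obs, 0.2)
  pp <- parameter_posterior(rej$accepted, rej$distances, obs)
  tr <- pp$sample[, "t_recent"]
  expect_true(all(tr >= 10 & tr <= 500))
  s <- pp$summary[pp$summary$parameter == "t_recent", ]
  expect_true(s$q025 <= s$median & s$median <= s$q975)
  expect_gt(s$median, 255)  # shifted towards the high-he_1 observation
})

test_that("a singular regression falls back to unadjusted quantiles", {
  set.seed(129)
  ref <- toy_ref(200, scen = 2)
  ref[, summary_names()] <- 0
  ref$na_1 <- 1:200  # one informative column so rejection works
  obs <- setNames(rep(0, 15), summary_names())
  obs["na_1"] <- 100
  expect_warning(rej <- abc_rejection(ref, obs, 0.5), "zero-variance")
  rej$accepted[, "na_1"] <- 5  # now constant among accepted: singular fit
  expect_warning(
    pp <- parameter_posterior(rej$accepted, rej$distances, obs,
                              parameters = "t_deep"),
    "singular|unadjusted")
  expect_true(all(pp$sample[, "t_deep"] >= 500))
})

test_that("generation-to-year conversion uses the six-year generation time", {
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(110), 660)
  expect_equal(generations_to_years(1820), 10920)
  expect_equal(generations_to_years(596), 3576)
  expect_error(generations_to_years(-1), "non-negative")
})

test_that("the PCA model check projects orthonormally and flags outliers", {
  set.seed(131)
  prior <- matrix(rnorm(500 * 15), 500, 15,
                  dimnames = list(NULL, summary_names()))
  post <- matrix(rnorm(200 * 15, 0, 0.5), 200, 15,
                 dimnames = list(NULL, summary_names()))
  obs <- setNames(rnorm(15, 0, 0.5), summary_names())
  chk <- pca_model_check(prior, post, obs)
  R <- chk$rotation
  expect_equal(t(R) %*% R, diag(ncol(R)), tolerance = 1e-8,
               ignore_attr = TRUE)
  far <- setNames(rep(10, 15), summary_names())
  expect_false(pca_model_check(prior, post, far)$inside)
})

test_that("observed points from the posterior cloud are inside ~95% of runs", {
  set.seed(132)
  inside <- replicate(100, {
    prior <- matrix(rnorm(200 * 15), 200, 15,
                    dimnames = list(NULL, summary_names()))
    post <- matrix(rnorm(120 * 15, 0, 0.6), 120, 15,
                   dimnames = list(NULL, summary_names()))
    obs <- setNames(rnorm(15, 0, 0.6), summary_names())
    pca_model_check(prior, post, obs)$inside
  })
  expect_gte(mean(inside), 0.85)
})

test_that("monomorphic data yield zero diversity, unit M and flagged theta", {
  tab <- genotype_table(matrix(100L, 12, 3), matrix(100L, 12, 3),
                        paste0("i", 1:12), paste0("L", 1:3),
                        rep(c("P1", "P2", "P3"), each = 4))
  s <- compute_observed_summaries(tab, c("P1", "P2", "P3"))
  expect_equal(unname(s[c("he_1", "he_2", "he_3")]), c(0, 0, 0))
  expect_equal(unname(s[c("m_1", "m_2", "m_3")]), c(1, 1, 1))
  expect_setequal(attr(s, "fst_undefined"),
                  c("fst_12", "fst_13", "fst_23"))
  expect_length(s, 15)
})
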