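test_that("prior draws respect bounds and the time ordering", {
  set.seed(111)
  spec <- scenario_spec("admixture")
  d <- sample_prior(spec, 10000)
  expect_true(all(d$N1 >= 10 & d$N1 <= 15000))
  expect_true(all(d$N2 <= 10000 & d$N3 <= 10000))
  expect_true(all(d$t_recent >= 10 & d$t_recent <= 500))
  expect_true(all(d$t_deep >= 500 & d$t_deep <= 15000))
  expect_true(all(d$t_recent < d$t_deep))
  expect_true(all(d$ra > 0 & d$ra < 1))
  expect_equal(mean(d$t_recent), (10 + 500) / 2, tolerance = 0.02)

  ddiv <- sample_prior(scenario_spec("divergence"), 100)
  expect_true(all(is.na(ddiv$ra)))
})

test_that("per-locus mutation draws stay inside their truncation bands", {
  set.seed(112)
  lr <- draw_locus_rates(runif(200, 1e-4, 1e-3), runif(200, 0.1, 0.3), 14)
  expect_true(all(lr$mu >= 1e-6 & lr$mu <= 1e-2))
  expect_true(all(lr$P >= 0.01 & lr$P <= 0.9))
})

test_that("a zero mutation rate yields monomorphic loci", {
  set.seed(113)
  params <- list(N1 = 500, N2 = 500, N3 = 500, t_recent = 100,
                 t_deep = 1000, ra = 0.5, n_anc = 500)
  g <- simulate_locus(params, 2, c(10, 10, 10), mu = 0, P = 0.5)
  expect_equal(length(unique(g)), 1)
  expect_error(simulate_locus(params, 3, c(10, 10, 10), 1e-3, 0.5),
               "invalid topology")
})

test_that("single-population diversity matches the SMM closed form", {
  # strict stepwise limit: equilibrium gene diversity 1 - 1/sqrt(1 + 8Nu)
  set.seed(114)
  he <- replicate(2000, {
    s <- badgerabc:::.sim_single_pop_cpp(100L, 1000, 2.5e-4, 1, 1L, 100L)$sizes
    p <- table(s) / length(s)
    (length(s) / (length(s) - 1)) * (1 - sum(p^2))
  })
  expect_lt(abs(mean(he) - (1 - 1 / sqrt(3))), 0.01)
})

test_that("first-coalescence waiting times follow the Kingman rate", {
  set.seed(115)
  N <- 500; n <- 10
  t2 <- replicate(3000, min(
    badgerabc:::.sim_single_pop_cpp(n, N, 0, 0.5, 1L, 100L)$coal_times))
  expect_equal(mean(t2), 4 * N / (n * (n - 1)), tolerance = 0.05)
})

test_that("mean diversity grows with the mutation rate", {
  set.seed(116)
  mean_he <- sapply(c(1e-4, 3e-4, 1e-3), function(mu) {
    mean(replicate(300, {
      s <- badgerabc:::.sim_single_pop_cpp(60L, 1000, mu, 0.3, 2L, 100L)$sizes
      p <- table(s) / length(s)
      1 - sum(p^2)
    }))
  })
  expect_true(all(diff(mean_he) > 0))
})

test_that("total admixture at a very recent time makes pop3 mirror pop1", {
  set.seed(117)
  draws <- data.frame(scenario = 2, N1 = 2000, N2 = 2000, N3 = 2000,
                      t_recent = 10, t_deep = 5000, ra = 1, n_anc = 2000,
                      mu_bar = 5e-4, p_bar = 0.2)
  draws <- draws[rep(1, 60), ]
  s <- simulate_summaries(draws, c(30, 30, 30), 14)
  expect_lt(abs(mean(s[, "fst_13"])), 0.02)
  expect_gt(mean(s[, "fst_12"]), 5 * abs(mean(s[, "fst_13"])))
})

test_that("reference tables are complete, deterministic and resumable", {
  specs <- list(scenario_spec("divergence"), scenario_spec("admixture"))
  ref <- build_reference_table(specs, 100, c(10, 10, 10), n_loci = 5,
                               seed = 42, chunk_size = 60)
  expect_equal(nrow(ref), 200)
  expect_equal(sum(ref$scenario == 1), 100)
  expect_false(anyNA(ref[, summary_names()]))

  ref2 <- build_reference_table(specs, 100, c(10, 10, 10), n_loci = 5,
                                seed = 42, chunk_size = 60)
  expect_identical(ref, ref2)

  # resume: a file holding only the first chunk is completed, not restarted
  full_path <- withr::local_tempfile(fileext = ".tsv")
  full <- build_reference_table(specs, 100, c(10, 10, 10), n_loci = 5,
                                seed = 42, chunk_size = 60, path = full_path)
  part_path <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(full_path)
  writeLines(lines[1:61], part_path)  # header + first chunk of 60
  resumed <- build_reference_table(specs, 100, c(10, 10, 10), n_loci = 5,
                                   seed = 42, chunk_size = 60,
                                   path = part_path)
  expect_equal(resumed, full, tolerance = 1e-12)
})

test_that("simulated datasets reproduce their stored summary vector in R", {
  set.seed(118)
  spec <- scenario_spec("admixture")
  d <- sample_prior(spec, 1)
  d$n_anc <- d$N2
  sim <- simulate_genotypes(as.list(d), 2, c(15, 20, 10), 6)
  s_cpp <- badgerabc:::.summaries_from_genes_cpp(
    sim$genes, as.integer(2 * c(15, 20, 10)), 2L)
  s_r <- compute_observed_summaries(sim$table, c("Pop1", "Pop2", "Pop3"))
  expect_equal(as.numeric(s_r), as.numeric(s_cpp), tolerance = 1e-10)
  expect_equal(names(s_r), summary_names())
})
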