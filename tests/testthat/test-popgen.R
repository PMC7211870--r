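test_that("allele frequencies count non-missing genes and match a naive counter", {
  tab <- genotype_table(matrix(c(10L, 10L)), matrix(c(10L, 12L)),
                        c("b1", "b2"), "L1", c("P", "P"))
  fr <- allele_frequencies(tab, "P")
  expect_equal(fr[["L1"]]$allele_counts, c(`10` = 3L, `12` = 1L))
  expect_equal(fr[["L1"]]$n_genes, 4L)

  set.seed(21)
  for (k in 1:10) {
    rt <- random_genotype_table(20, 4, rep(c("A", "B"), 10),
                                missing_rate = 0.1)
    for (pop in c("A", "B")) {
      fr <- allele_frequencies(rt, pop)
      for (j in 1:4)
        expect_equal(fr[[j]]$allele_counts, naive_allele_counts(rt, pop, j))
    }
  }
})

test_that("heterozygosities follow Nei's unbiased estimator", {
  mono <- genotype_table(matrix(5L, 3), matrix(5L, 3),
                         paste0("i", 1:3), "L1", rep("P", 3))
  h <- heterozygosities(mono, "P")
  expect_equal(unname(h$He), 0)
  expect_equal(unname(h$Ho), 0)

  tab <- genotype_table(matrix(c(1L, 1L)), matrix(c(2L, 2L)),
                        c("x", "y"), "L1", c("P", "P"))
  h <- heterozygosities(tab, "P")
  expect_equal(unname(h$Ho), 1)
  expect_equal(unname(h$He), (4 / 3) * 0.5, tolerance = 1e-12)
})

test_that("Weir-Cockerham f is 1 with no heterozygotes and ~0 under HW", {
  allhom <- genotype_table(matrix(rep(c(1L, 2L), each = 5)),
                           matrix(rep(c(1L, 2L), each = 5)),
                           paste0("i", 1:10), "L1", rep("P", 10))
  expect_equal(fis_weir_cockerham(allhom, "P")$overall, 1)

  set.seed(31)
  n <- 10000
  g1 <- sample(c(100L, 102L), n, TRUE)
  g2 <- sample(c(100L, 102L), n, TRUE)
  hw <- genotype_table(cbind(g1), cbind(g2), paste0("i", 1:n), "L1",
                       rep("P", n))
  expect_lt(abs(fis_weir_cockerham(hw, "P")$overall), 0.02)
})

test_that("f agrees with the independent ANOVA-route estimator", {
  set.seed(32)
  for (k in 1:20) {
    rt <- random_genotype_table(20, 3, rep("A", 20), missing_rate = 0.05)
    expect_equal(fis_weir_cockerham(rt, "A")$overall,
                 fis_anova_oracle(rt, "A"), tolerance = 1e-10)
  }
})

test_that("pairwise theta spans its range and matches the ANOVA oracle", {
  set.seed(41)
  half <- random_genotype_table(15, 4, rep("A", 15))
  dup <- genotype_table(rbind(half$allele1, half$allele1),
                        rbind(half$allele2, half$allele2),
                        paste0("i", 1:30), half$locus_names,
                        rep(c("A", "B"), each = 15))
  expect_lt(abs(pairwise_fst(dup, "A", "B")$theta), 0.05)

  fixed <- fixed_difference_table()
  expect_equal(pairwise_fst(fixed, "A", "B")$theta, 1)

  for (k in 1:20) {
    rt <- random_genotype_table(20, 3, rep(c("A", "B"), 10),
                                missing_rate = 0.05)
    expect_equal(pairwise_fst(rt, "A", "B")$theta,
                 theta_anova_oracle(rt, "A", "B"), tolerance = 1e-10)
  }
})

test_that("theta permutation test is calibrated against label exchange", {
  set.seed(42)
  rt <- random_genotype_table(30, 4, rep(c("A", "B"), 15))
  p <- pairwise_fst(rt, "A", "B", n_permutations = 99)$p_value
  expect_gt(p, 0.01)  # no real differentiation: p should not be extreme
  fixed <- fixed_difference_table()
  pf <- pairwise_fst(fixed, "A", "B", n_permutations = 99)$p_value
  expect_lt(pf, 0.05)
})

test_that("Jost's D spans its range and matches the hand formula", {
  fixed <- fixed_difference_table()
  expect_equal(josts_d(fixed, "A", "B")$D, 1)

  set.seed(51)
  half <- random_genotype_table(50, 3, rep("A", 50),
                                allele_pool = 100 + 2 * (0:2))
  dup <- genotype_table(rbind(half$allele1, half$allele1),
                        rbind(half$allele2, half$allele2),
                        paste0("i", 1:100), half$locus_names,
                        rep(c("A", "B"), each = 50))
  expect_lt(abs(josts_d(dup, "A", "B")$D), 0.05)

  for (k in 1:20) {
    rt <- random_genotype_table(20, 3, rep(c("A", "B"), 10))
    expect_equal(josts_d(rt, "A", "B")$D, jost_d_oracle(rt, "A", "B"),
                 tolerance = 1e-12)
  }
})

test_that("M-ratio follows k/(r+1) on the repeat-unit ladder", {
  expect_equal(m_ratio(c(`100` = 4)), 1)
  expect_equal(m_ratio(c(`100` = 1, `102` = 2, `104` = 1), 2), 1)
  expect_equal(m_ratio(c(`100` = 1, `120` = 1), 2), 2 / 11)
  expect_error(m_ratio(integer(0)), "empty locus")
  expect_warning(m_ratio(c(`100` = 1, `103` = 1), 2), "not divisible")
})

test_that("delta-mu-squared is the mean squared repeat-unit difference", {
  a <- genotype_table(matrix(20L, 5), matrix(20L, 5), paste0("a", 1:5),
                      "L1", rep("A", 5))
  b <- genotype_table(matrix(26L, 5), matrix(26L, 5), paste0("b", 1:5),
                      "L1", rep("B", 5))
  tab <- genotype_table(rbind(a$allele1, b$allele1),
                        rbind(a$allele2, b$allele2),
                        c(a$individual_ids, b$individual_ids), "L1",
                        c(a$population_labels, b$population_labels))
  expect_equal(delta_mu_squared(tab, "A", "B", 2)$delta_mu_sq, 9)
  expect_equal(delta_mu_squared(tab, "A", "A", 2)$delta_mu_sq, 0)
  expect_gt(delta_mu_squared(fixed_difference_table(), "A", "B")$delta_mu_sq, 0)

  set.seed(61)
  rt <- random_genotype_table(20, 4, rep(c("A", "B"), 10))
  direct <- mean(sapply(1:4, function(j) {
    gA <- c(rt$allele1[rt$population_labels == "A", j],
            rt$allele2[rt$population_labels == "A", j])
    gB <- c(rt$allele1[rt$population_labels == "B", j],
            rt$allele2[rt$population_labels == "B", j])
    ((mean(gA) - mean(gB)) / 2)^2
  }))
  expect_equal(delta_mu_squared(rt, "A", "B", 2)$delta_mu_sq, direct,
               tolerance = 1e-12)
})

test_that("allele-frequency Z tests match the pooled-proportion formula", {
  # 50 diploids each; allele u at 0.6 vs 0.4
  mkpop <- function(nu, n, lab, ids) {
    genes <- c(rep(100L, nu), rep(102L, 2 * n - nu))
    genotype_table(cbind(genes[seq_len(n) * 2 - 1]),
                   cbind(genes[seq_len(n) * 2]), ids, "L1", rep(lab, n))
  }
  A <- mkpop(60, 50, "A", paste0("a", 1:50))
  B <- mkpop(40, 50, "B", paste0("b", 1:50))
  z <- allele_freq_ztests(A, B)
  expect_equal(z$Z[z$allele == 100], 0.2 / sqrt(0.5 * 0.5 * 0.02),
               tolerance = 1e-12)

  same <- allele_freq_ztests(A, A)
  expect_true(all(same$Z == 0))
  expect_false(any(same$significant))
})

test_that("multi-locus statistics are invariant to locus and individual order", {
  set.seed(71)
  rt <- random_genotype_table(24, 5, rep(c("A", "B"), 12),
                              missing_rate = 0.05)
  perm_loci <- sample(5); perm_ind <- sample(24)
  shuffled <- genotype_table(rt$allele1[perm_ind, perm_loci],
                             rt$allele2[perm_ind, perm_loci],
                             rt$individual_ids[perm_ind],
                             rt$locus_names[perm_loci],
                             rt$population_labels[perm_ind])
  expect_equal(pairwise_fst(rt, "A", "B")$theta,
               pairwise_fst(shuffled, "A", "B")$theta, tolerance = 1e-12)
  expect_equal(josts_d(rt, "A", "B")$D, josts_d(shuffled, "A", "B")$D,
               tolerance = 1e-12)
  expect_equal(heterozygosities(rt, "A")$mean_He,
               heterozygosities(shuffled, "A")$mean_He, tolerance = 1e-12)
  expect_equal(sort(population_summary(rt)$He),
               sort(population_summary(shuffled)$He), tolerance = 1e-12)
})

test_that("the population summary table reports N as mean typed individuals", {
  tab <- genotype_table(matrix(c(1L, 1L, NA, 2L), 2), matrix(c(1L, 2L, NA, 2L), 2),
                        c("x", "y"), c("L1", "L2"), c("P", "P"))
  s <- population_summary(tab)
  expect_equal(s$N, 1.5)  # 2 typed at L1, 1 at L2
  expect_named(s, c("population", "N", "Na", "He", "Ho", "Fis"))
})
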