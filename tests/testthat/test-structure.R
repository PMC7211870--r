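toy_loglik <- function() {
  data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
             lnP = c(-100, -100, -50, -52, -49, -49))
}

test_that("delta-K reproduces the hand-computed toy value", {
  dk <- evanno_delta_k(toy_loglik())
  # replicate-wise second differences at K=2: |-49 + 100 - 100| = 49 and
  # |-49 + 104 - 100| = 45; mean 47; sd of (-50, -52) = sqrt(2)
  expect_equal(dk$delta_K[dk$K == 2], 47 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(dk$delta_K[dk$K == 1]))
  expect_true(is.na(dk$delta_K[dk$K == 3]))
})

test_that("delta-K of a linear likelihood profile is ~0 and shift-invariant", {
  set.seed(101)
  tbl <- data.frame(K = rep(1:6, each = 5), replicate = rep(1:5, 6))
  tbl$lnP <- -1000 + 20 * tbl$K + rnorm(nrow(tbl), 0, 0.5)
  dk <- evanno_delta_k(tbl)
  interior <- dk$delta_K[!is.na(dk$delta_K)]
  expect_true(all(interior < 3))  # second difference of a line is noise only

  shifted <- tbl; shifted$lnP <- shifted$lnP + 12345
  expect_equal(evanno_delta_k(shifted)$delta_K, dk$delta_K,
               tolerance = 1e-9)
})

test_that("a kink at K = 2 dominates the delta-K profile", {
  set.seed(102)
  tbl <- data.frame(K = rep(1:5, each = 4), replicate = rep(1:4, 5))
  means <- c(-2000, -1200, -1150, -1100, -1050)[tbl$K]
  tbl$lnP <- means + rnorm(nrow(tbl), 0, 5)
  dk <- evanno_delta_k(tbl)
  expect_equal(dk$K[which.max(dk$delta_K)], 2)
})

test_that("delta-K requires consecutive K with replicates, flags zero sd", {
  expect_error(evanno_delta_k(data.frame(K = c(1, 1, 3, 3, 4, 4),
                                         replicate = rep(1:2, 3),
                                         lnP = rnorm(6))), "consecutive")
  flat <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                     lnP = c(-10, -10, -20, -20, -30, -30))
  dk <- evanno_delta_k(flat)
  expect_true(dk$flagged[dk$K == 2])
  expect_true(is.na(dk$delta_K[dk$K == 2]))
})

test_that("log-likelihood tables parse from delimited text", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("K\treplicate\tlnP", "1\t1\t-100", "1\t2\t-101",
               "2\t1\t-50", "2\t2\t-51", "3\t1\t-49", "3\t2\t-49.5"), f)
  tbl <- read_loglik_table(f)
  expect_equal(names(tbl), c("K", "replicate", "lnP"))
  expect_equal(nrow(tbl), 6)
  expect_silent(evanno_delta_k(tbl))
})

test_that("Q-score thresholding is inclusive at 0.85 and monotone", {
  q <- data.frame(id = c("a", "b", "c", "d"),
                  Q1 = c(1.0, 0.85, 0.84, 0.10),
                  Q2 = c(0.0, 0.15, 0.16, 0.90))
  part <- q_threshold_partition(q, 1, 0.85)
  expect_equal(part$group, c("native", "native", "admixed", "admixed"))
  # monotone: raising the threshold never grows the native group
  sizes <- sapply(c(0.5, 0.7, 0.85, 0.95), function(th)
    sum(q_threshold_partition(q, 1, th)$group == "native"))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sum(table(part$group)), nrow(q))

  bad <- q; bad$Q1[1] <- 0.7
  expect_error(q_threshold_partition(bad, 1), "sum to 1")
})

test_that("Q matrices parse from both delimited text and STRUCTURE blocks", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,Q1,Q2", "a,0.9,0.1", "b,0.2,0.8"), f)
  q <- read_qmatrix(f)
  expect_equal(q$Q1, c(0.9, 0.2))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("some header", "Inferred ancestry of individuals:",
               "    Label (%Miss) Pop:  Inferred clusters",
               "  1 badger_1  (0)  1 :  0.97 0.03",
               "  2 badger_2  (2)  1 :  0.55 0.45"), f2)
  q2 <- read_qmatrix(f2)
  expect_equal(q2$id, c("badger_1", "badger_2"))
  expect_equal(q2$Q2, c(0.03, 0.45))
})
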