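# Fixture builders and independently coded oracles used across the suite.

random_genotype_table <- function(n_ind, n_loci, pops,
                                  allele_pool = 100 + 2 * (0:5),
                                  missing_rate = 0) {
  a1 <- matrix(sample(allele_pool, n_ind * n_loci, TRUE), n_ind, n_loci)
  a2 <- matrix(sample(allele_pool, n_ind * n_loci, TRUE), n_ind, n_loci)
  if (missing_rate > 0) {
    miss <- matrix(runif(n_ind * n_loci) < missing_rate, n_ind, n_loci)
    a1[miss] <- NA; a2[miss] <- NA
  }
  genotype_table(a1, a2, paste0("ind", seq_len(n_ind)),
                 paste0("L", seq_len(n_loci)), pops)
}

# naive double-loop allele counter
naive_allele_counts <- function(tab, pop, locus_j) {
  counts <- integer(0)
  for (i in seq_along(tab$individual_ids)) {
    if (tab$population_labels[i] != pop) next
    for (a in c(tab$allele1[i, locus_j], tab$allele2[i, locus_j])) {
      if (is.na(a)) next
      key <- as.character(a)
      counts[key] <- if (key %in% names(counts)) counts[key] + 1L else 1L
    }
  }
  counts[order(as.numeric(names(counts)))]
}

# Weir-Cockerham theta via the ANOVA mean-squares route (independent of the
# package's direct variance-component formulas)
theta_anova_oracle <- function(tab, A, B) {
  iA <- which(tab$population_labels == A)
  iB <- which(tab$population_labels == B)
  P <- I <- G <- 0; r <- 2
  for (j in seq_along(tab$locus_names)) {
    gA1 <- tab$allele1[iA, j]; gA2 <- tab$allele2[iA, j]
    gB1 <- tab$allele1[iB, j]; gB2 <- tab$allele2[iB, j]
    keepA <- !is.na(gA1); keepB <- !is.na(gB1)
    gA1 <- gA1[keepA]; gA2 <- gA2[keepA]
    gB1 <- gB1[keepB]; gB2 <- gB2[keepB]
    alle <- sort(unique(c(gA1, gA2, gB1, gB2)))
    if (length(alle) < 2) next
    nA <- sum(keepA); nB <- sum(keepB); n. <- nA + nB
    for (u in alle) {
      yA <- (gA1 == u) + (gA2 == u); yB <- (gB1 == u) + (gB2 == u)
      pA <- mean(yA) / 2; pB <- mean(yB) / 2
      pbar <- (nA * pA + nB * pB) / n.
      SSG <- 0.5 * sum(c(yA, yB) == 1)
      SSI <- sum(2 * (yA / 2 - pA)^2) + sum(2 * (yB / 2 - pB)^2)
      SSP <- 2 * nA * (pA - pbar)^2 + 2 * nB * (pB - pbar)^2
      MSG <- SSG / n.; MSI <- SSI / (n. - r); MSP <- SSP / (r - 1)
      nc <- (n. - (nA^2 + nB^2) / n.) / (r - 1)
      G <- G + MSG
      I <- I + (MSI - MSG) / 2
      P <- P + (MSP - MSI) / (2 * nc)
    }
  }
  P / (P + I + G)
}

fis_anova_oracle <- function(tab, A) {
  iA <- which(tab$population_labels == A)
  I <- G <- 0
  for (j in seq_along(tab$locus_names)) {
    g1 <- tab$allele1[iA, j]; g2 <- tab$allele2[iA, j]
    keep <- !is.na(g1)
    g1 <- g1[keep]; g2 <- g2[keep]
    alle <- sort(unique(c(g1, g2)))
    if (length(alle) < 2) next
    n <- sum(keep)
    for (u in alle) {
      y <- (g1 == u) + (g2 == u); p <- mean(y) / 2
      SSG <- 0.5 * sum(y == 1); SSI <- sum(2 * (y / 2 - p)^2)
      MSG <- SSG / n; MSI <- SSI / (n - 1)
      G <- G + MSG; I <- I + (MSI - MSG) / 2
    }
  }
  I / (I + G)
}

# literal per-locus Jost's D (Nei-Chesser corrected), arithmetic mean
jost_d_oracle <- function(tab, A, B) {
  iA <- which(tab$population_labels == A)
  iB <- which(tab$population_labels == B)
  vals <- c()
  for (j in seq_along(tab$locus_names)) {
    gA <- c(tab$allele1[iA, j], tab$allele2[iA, j])
    gB <- c(tab$allele1[iB, j], tab$allele2[iB, j])
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    nA <- length(gA) / 2; nB <- length(gB) / 2
    if (nA < 1 || nB < 1) next
    alle <- sort(unique(c(gA, gB)))
    pA <- sapply(alle, function(u) mean(gA == u))
    pB <- sapply(alle, function(u) mean(gB == u))
    nh <- 2 / (1 / nA + 1 / nB)
    Hs <- 1 - (sum(pA^2) + sum(pB^2)) / 2
    Hs_e <- 2 * nh / (2 * nh - 1) * Hs
    Ht <- 1 - sum(((pA + pB) / 2)^2)
    Ht_e <- Ht + Hs_e / (4 * nh)
    if (1 - Hs_e <= 0) next
    vals <- c(vals, (Ht_e - Hs_e) / (1 - Hs_e) * 2)
  }
  mean(vals)
}

# brute-force pairwise difference count between two sequences, N/gap excluded
pairwise_diff_oracle <- function(s1, s2) {
  x <- strsplit(toupper(s1), "")[[1]]
  y <- strsplit(toupper(s2), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  sum(x[ok] != y[ok])
}

# a small genotype table where the two populations are fixed for different
# alleles at every locus
fixed_difference_table <- function(n_per_pop = 8, n_loci = 4) {
  a1 <- cbind(matrix(100L, n_per_pop, n_loci))
  b1 <- cbind(matrix(120L, n_per_pop, n_loci))
  genotype_table(rbind(a1, b1), rbind(a1, b1),
                 paste0("i", seq_len(2 * n_per_pop)),
                 paste0("L", seq_len(n_loci)),
                 rep(c("A", "B"), each = n_per_pop))
}
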