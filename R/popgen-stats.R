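#' Per-locus allele frequencies for one population
#'
#' Counts allele copies over non-missing genotypes.  An individual missing a
#' locus is excluded from that locus only.
#'
#' @param table a [genotype_table()].
#' @param population a population label in `table`.
#' @return A list with one element per locus: `locus_name`, `allele_counts`
#'   (named integer vector, names are allele sizes), `n_genes` (2 x typed
#'   individuals).  Loci with zero typed individuals have `n_genes = 0` and
#'   an empty count vector; they are flagged via attribute `excluded_loci`.
#' @examples
#' gt <- genotype_table(matrix(c(10L, 10L), 2), matrix(c(10L, 12L), 2),
#'                      c("b1", "b2"), "L1", c("P", "P"))
#' allele_frequencies(gt, "P")[[1]]$allele_counts
#' @export
allele_frequencies <- function(table, population) {
  sub <- subset_population(table, population)
  res <- lapply(seq_along(sub$locus_names), function(j) {
    a <- c(sub$allele1[, j], sub$allele2[, j])
    a <- a[!is.na(a)]
    counts <- table(a)
    list(locus_name = sub$locus_names[j],
         allele_counts = setNames(as.integer(counts), names(counts)),
         n_genes = length(a))
  })
  names(res) <- sub$locus_names
  excluded <- sub$locus_names[vapply(res, function(x) x$n_genes == 0, TRUE)]
  attr(res, "excluded_loci") <- excluded
  res
}

# Nei's unbiased gene diversity from a count vector: (2n/(2n-1))(1 - sum p^2)
unbiased_gene_diversity <- function(counts, n_genes) {
  if (n_genes < 2) return(NA_real_)
  p <- counts / n_genes
  (n_genes / (n_genes - 1)) * (1 - sum(p^2))
}

#' Observed and expected heterozygosity per locus
#'
#' `Ho` is the fraction of typed individuals that are heterozygous; `He` is
#' Nei's unbiased gene diversity \eqn{(2n/(2n-1))(1 - \sum p_i^2)}.
#' Across-locus means are arithmetic over loci with data.
#'
#' @inheritParams allele_frequencies
#' @return A list with per-locus vectors `He`, `Ho` and scalars `mean_He`,
#'   `mean_Ho`.  Monomorphic loci have `He = Ho = 0`.
#' @export
heterozygosities <- function(table, population) {
  sub <- subset_population(table, population)
  freqs <- allele_frequencies(table, population)
  He <- vapply(freqs, function(f) {
    if (f$n_genes == 0) return(NA_real_)
    unbiased_gene_diversity(f$allele_counts, f$n_genes)
  }, 0)
  Ho <- vapply(seq_along(sub$locus_names), function(j) {
    a1 <- sub$allele1[, j]; a2 <- sub$allele2[, j]
    typed <- !is.na(a1)
    if (!any(typed)) return(NA_real_)
    mean(a1[typed] != a2[typed])
  }, 0)
  names(Ho) <- sub$locus_names
  list(He = He, Ho = Ho,
       mean_He = mean(He, na.rm = TRUE), mean_Ho = mean(Ho, na.rm = TRUE))
}

# Weir & Cockerham (1984) within-population components for one locus
# (single population, r = 1): per allele
#   b = (n/(n-1)) (p(1-p) - (2n-1)/(4n) hbar),  c = hbar/2
# where hbar is the observed frequency of heterozygotes carrying the allele.
wc_single_pop_components <- function(a1, a2) {
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  n <- length(a1)
  if (n < 2) return(NULL)
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2) return(NULL)  # monomorphic: f undefined
  genes <- c(a1, a2)
  het <- a1 != a2
  b <- c <- numeric(length(alleles))
  for (k in seq_along(alleles)) {
    u <- alleles[k]
    p <- mean(genes == u)
    hbar <- mean(het & (a1 == u | a2 == u))
    b[k] <- (n / (n - 1)) * (p * (1 - p) - (2 * n - 1) / (4 * n) * hbar)
    c[k] <- hbar / 2
  }
  list(b = sum(b), c = sum(c))
}

#' Weir-Cockerham inbreeding coefficient (f) for one population
#'
#' The within-population fixation index of Weir & Cockerham (1984),
#' \eqn{\hat f = 1 - \sum c / \sum (b + c)}, with variance components summed
#' over alleles and loci before taking the ratio (FSTAT's multi-locus
#' combination).  Monomorphic loci carry no information and are excluded.
#'
#' @inheritParams allele_frequencies
#' @return A list with `per_locus` (named vector of per-locus f, `NA` where
#'   undefined) and `overall` (the components-summed multi-locus value).
#' @export
fis_weir_cockerham <- function(table, population) {
  sub <- subset_population(table, population)
  B <- C <- 0
  per_locus <- setNames(rep(NA_real_, length(sub$locus_names)),
                        sub$locus_names)
  for (j in seq_along(sub$locus_names)) {
    comp <- wc_single_pop_components(sub$allele1[, j], sub$allele2[, j])
    if (is.null(comp)) next
    if (comp$b + comp$c > 0)
      per_locus[j] <- 1 - comp$c / (comp$b + comp$c)
    B <- B + comp$b; C <- C + comp$c
  }
  overall <- if (B + C > 0) 1 - C / (B + C) else NA_real_
  list(per_locus = per_locus, overall = overall)
}

# Weir & Cockerham (1984) two-population variance components (a, b, c)
# summed over alleles for one locus.  Returns NULL where uninformative.
wc_pair_components_r <- function(a1A, a2A, a1B, a2B) {
  tA <- !is.na(a1A); tB <- !is.na(a1B)
  a1A <- a1A[tA]; a2A <- a2A[tA]; a1B <- a1B[tB]; a2B <- a2B[tB]
  nA <- length(a1A); nB <- length(a1B)
  if (nA < 1 || nB < 1) return(NULL)
  alleles <- sort(unique(c(a1A, a2A, a1B, a2B)))
  if (length(alleles) < 2) return(NULL)
  genesA <- c(a1A, a2A); genesB <- c(a1B, a2B)
  hetA <- a1A != a2A; hetB <- a1B != a2B
  nbar <- (nA + nB) / 2
  nc <- (nA + nB) - (nA^2 + nB^2) / (nA + nB)
  A <- B <- C <- 0
  for (u in alleles) {
    p1 <- mean(genesA == u); p2 <- mean(genesB == u)
    h1 <- mean(hetA & (a1A == u | a2A == u))
    h2 <- mean(hetB & (a1B == u | a2B == u))
    pbar <- (nA * p1 + nB * p2) / (nA + nB)
    s2 <- (nA * (p1 - pbar)^2 + nB * (p2 - pbar)^2) / nbar
    hbar <- (nA * h1 + nB * h2) / (nA + nB)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    A <- A + a; B <- B + b; C <- C + hbar / 2
  }
  list(a = A, b = B, c = C)
}

#' Pairwise Weir-Cockerham theta between two populations
#'
#' Multi-allele, multi-locus \eqn{\hat\theta} with variance components
#' summed over alleles and loci before the ratio.  An optional permutation
#' test shuffles population labels across individuals.
#'
#' @param table a [genotype_table()].
#' @param popA,popB population labels.
#' @param n_permutations number of label permutations for the p-value
#'   (0 skips the test; 420 is the study default).
#' @return A list with `theta`, `per_locus` theta values, and (if permuted)
#'   `p_value`.
#' @export
pairwise_fst <- function(table, popA, popB, n_permutations = 0) {
  theta_of <- function(labels) {
    iA <- which(labels == popA); iB <- which(labels == popB)
    A <- B <- C <- 0
    for (j in seq_along(table$locus_names)) {
      comp <- wc_pair_components_r(table$allele1[iA, j], table$allele2[iA, j],
                                   table$allele1[iB, j], table$allele2[iB, j])
      if (is.null(comp)) next
      A <- A + comp$a; B <- B + comp$b; C <- C + comp$c
    }
    if (A + B + C == 0) return(NA_real_)
    A / (A + B + C)
  }
  keep <- table$population_labels %in% c(popA, popB)
  if (sum(table$population_labels == popA) == 0 ||
      sum(table$population_labels == popB) == 0)
    stop("both populations must have typed individuals")
  per_locus <- setNames(rep(NA_real_, length(table$locus_names)),
                        table$locus_names)
  iA <- which(table$population_labels == popA)
  iB <- which(table$population_labels == popB)
  any_locus <- FALSE
  for (j in seq_along(table$locus_names)) {
    comp <- wc_pair_components_r(table$allele1[iA, j], table$allele2[iA, j],
                                 table$allele1[iB, j], table$allele2[iB, j])
    if (is.null(comp)) next
    any_locus <- TRUE
    if (comp$a + comp$b + comp$c != 0)
      per_locus[j] <- comp$a / (comp$a + comp$b + comp$c)
  }
  shared_typed <- any(vapply(seq_along(table$locus_names), function(j) {
    any(!is.na(table$allele1[iA, j])) && any(!is.na(table$allele1[iB, j]))
  }, TRUE))
  if (!shared_typed) stop("populations share no typed loci")
  obs <- theta_of(table$population_labels)
  res <- list(theta = obs, per_locus = per_locus)
  if (n_permutations > 0) {
    labs <- table$population_labels
    idx <- which(keep)
    perm <- vapply(seq_len(n_permutations), function(i) {
      labs[idx] <- sample(labs[idx])
      theta_of(labs)
    }, 0)
    res$p_value <- (1 + sum(perm >= obs, na.rm = TRUE)) / (n_permutations + 1)
  }
  res
}

#' Jost's D between two populations
#'
#' Per-locus \eqn{D_{est} = \frac{H_T - H_S}{1 - H_S} \cdot \frac{k}{k-1}}
#' with \eqn{k = 2} populations and Nei-Chesser bias-corrected \eqn{H_S}
#' and \eqn{H_T} (harmonic-mean sample size).  Loci are combined by the
#' arithmetic mean of per-locus values by default; the harmonic-mean
#' variant is available.
#'
#' @inheritParams pairwise_fst
#' @param combine `"arithmetic"` (default) or `"harmonic"` across-locus
#'   mean of the per-locus estimates.
#' @return A list with `D` and `per_locus` values.
#' @export
josts_d <- function(table, popA, popB, combine = c("arithmetic", "harmonic")) {
  combine <- match.arg(combine)
  iA <- which(table$population_labels == popA)
  iB <- which(table$population_labels == popB)
  if (length(iA) == 0 || length(iB) == 0)
    stop("both populations must have typed individuals")
  per_locus <- setNames(rep(NA_real_, length(table$locus_names)),
                        table$locus_names)
  for (j in seq_along(table$locus_names)) {
    gA <- c(table$allele1[iA, j], table$allele2[iA, j])
    gB <- c(table$allele1[iB, j], table$allele2[iB, j])
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    nA <- length(gA) / 2; nB <- length(gB) / 2
    if (nA < 1 || nB < 1) next
    alleles <- sort(unique(c(gA, gB)))
    pA <- vapply(alleles, function(u) mean(gA == u), 0)
    pB <- vapply(alleles, function(u) mean(gB == u), 0)
    ntilde <- 2 / (1 / nA + 1 / nB)
    Hs <- 1 - mean(c(sum(pA^2), sum(pB^2)))
    Hs_est <- (2 * ntilde / (2 * ntilde - 1)) * Hs
    Ht <- 1 - sum(((pA + pB) / 2)^2)
    Ht_est <- Ht + Hs_est / (4 * ntilde)
    if (1 - Hs_est <= 0) {
      warning("locus ", table$locus_names[j],
              ": H_S estimate is 1, excluded from Jost's D")
      next
    }
    per_locus[j] <- (Ht_est - Hs_est) / (1 - Hs_est) * 2
  }
  vals <- per_locus[!is.na(per_locus)]
  D <- if (combine == "arithmetic") mean(vals)
       else length(vals) / sum(1 / vals)
  list(D = D, per_locus = per_locus)
}

#' Garza-Williamson M-ratio for one locus
#'
#' \eqn{M = k / (r + 1)} with \eqn{k} the number of distinct alleles and
#' \eqn{r} the allele-size range in repeat units.  Allele sizes are
#' converted to repeat units by the locus motif length; size differences
#' not divisible by the motif are rounded with a warning.
#'
#' @param freqs one locus element of [allele_frequencies()] (a list with
#'   `allele_counts`), or a named count vector.
#' @param motif_length repeat motif length in base pairs (default 2).
#' @return M in (0, 1].
#' @examples
#' m_ratio(list(allele_counts = c(`100` = 2, `102` = 1, `104` = 3)), 2)
#' @export
m_ratio <- function(freqs, motif_length = 2) {
  counts <- if (is.list(freqs)) freqs$allele_counts else freqs
  if (length(counts) == 0) stop("empty locus: no alleles observed")
  sizes <- as.numeric(names(counts))
  k <- length(sizes)
  span <- max(sizes) - min(sizes)
  if (span %% motif_length != 0) {
    warning("allele-size range not divisible by motif length; rounding")
  }
  r <- round(span / motif_length)
  k / (r + 1)
}

#' Goldstein's delta-mu-squared distance between two populations
#'
#' Per locus, the squared difference in mean allele size (in repeat units)
#' between the two populations, averaged across loci typed in both.
#'
#' @inheritParams pairwise_fst
#' @param motif_length repeat motif length in base pairs.
#' @return A list with `delta_mu_sq` and `per_locus` values.
#' @export
delta_mu_squared <- function(table, popA, popB, motif_length = 2) {
  iA <- which(table$population_labels == popA)
  iB <- which(table$population_labels == popB)
  per_locus <- setNames(rep(NA_real_, length(table$locus_names)),
                        table$locus_names)
  for (j in seq_along(table$locus_names)) {
    gA <- c(table$allele1[iA, j], table$allele2[iA, j])
    gB <- c(table$allele1[iB, j], table$allele2[iB, j])
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    if (length(gA) == 0 || length(gB) == 0) next
    per_locus[j] <- ((mean(gA) - mean(gB)) / motif_length)^2
  }
  if (all(is.na(per_locus))) stop("populations share no typed loci")
  list(delta_mu_sq = mean(per_locus, na.rm = TRUE), per_locus = per_locus)
}

#' Two-proportion Z tests of allele frequencies between two samples
#'
#' For every allele at every shared locus, tests equality of allele
#' frequencies between the two tables with the pooled two-proportion
#' Z statistic
#' \eqn{Z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/2n_1 + 1/2n_2)}}.
#' P-values are corrected for multiple comparisons across all allele-locus
#' tests (Bonferroni by default).
#'
#' @param tableA,tableB two [genotype_table()]s sharing locus names (all
#'   individuals in each are used regardless of label).
#' @param correction a method for [stats::p.adjust()].
#' @return A data frame with columns `locus`, `allele`, `p1`, `p2`, `Z`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
allele_freq_ztests <- function(tableA, tableB, correction = "bonferroni") {
  shared <- intersect(tableA$locus_names, tableB$locus_names)
  if (length(shared) == 0) stop("tables share no loci")
  rows <- list()
  for (loc in shared) {
    jA <- match(loc, tableA$locus_names); jB <- match(loc, tableB$locus_names)
    gA <- c(tableA$allele1[, jA], tableA$allele2[, jA])
    gB <- c(tableB$allele1[, jB], tableB$allele2[, jB])
    gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
    if (length(gA) == 0 || length(gB) == 0) next
    for (u in sort(unique(c(gA, gB)))) {
      p1 <- mean(gA == u); p2 <- mean(gB == u)
      pp <- (sum(gA == u) + sum(gB == u)) / (length(gA) + length(gB))
      if (pp == 0 || pp == 1) next  # allele fixed or absent in the pool
      se <- sqrt(pp * (1 - pp) * (1 / length(gA) + 1 / length(gB)))
      Z <- (p1 - p2) / se
      rows[[length(rows) + 1]] <-
        data.frame(locus = loc, allele = u, p1 = p1, p2 = p2, Z = Z,
                   p_value = 2 * pnorm(-abs(Z)))
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = correction)
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}

#' Per-population summary table of standard indices
#'
#' One row per population: `N` (mean typed individuals per locus, possibly
#' fractional under missing data), mean allele number `Na`, mean expected
#' and observed heterozygosity `He` and `Ho`, and the Weir-Cockerham
#' fixation index `Fis`.
#'
#' @param table a [genotype_table()].
#' @param populations population labels to report (default all).
#' @return A data frame with columns `population`, `N`, `Na`, `He`, `Ho`,
#'   `Fis`.
#' @export
population_summary <- function(table, populations = NULL) {
  if (is.null(populations)) populations <- unique(table$population_labels)
  rows <- lapply(populations, function(pop) {
    sub <- subset_population(table, pop)
    typed <- !is.na(sub$allele1)
    N <- mean(colSums(typed))
    freqs <- allele_frequencies(table, pop)
    informative <- vapply(freqs, function(f) f$n_genes > 0, TRUE)
    if (!any(informative))
      stop("population ", pop, " has no typed genotypes at any locus")
    Na <- mean(vapply(freqs[informative],
                      function(f) length(f$allele_counts), 0))
    het <- heterozygosities(table, pop)
    fis <- fis_weir_cockerham(table, pop)
    data.frame(population = pop, N = N, Na = Na,
               He = het$mean_He, Ho = het$mean_Ho, Fis = fis$overall)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
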