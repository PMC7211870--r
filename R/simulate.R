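#' Default prior bounds for the demographic scenarios
#'
#' Uniform prior bounds used throughout: diploid effective sizes
#' `N1` (British) in \[10, 15000\], `N2` and `N3` (the two Irish
#' sub-populations) in \[10, 10000\]; the recent event time (`t1` for the
#' divergence topology, `ta` for admixture) in \[10, 500\] generations
#' before present; the deep split (`t2`/`td`) in \[500, 15000\]; the
#' admixture proportion `ra` in (0, 1).  Mutation hyper-priors follow the
#' standard microsatellite defaults: the across-locus mean rate
#' `mu_bar` uniform on \[1e-4, 1e-3\] per generation with per-locus rates
#' Gamma(shape 2) around it, and the mean geometric step parameter `p_bar`
#' uniform on \[0.1, 0.3\] with per-locus values Gamma(shape 2) truncated
#' to (0.01, 0.9).
#'
#' @return A named list of length-2 numeric bounds.
#' @export
default_priors <- function() {
  list(N1 = c(10, 15000), N2 = c(10, 10000), N3 = c(10, 10000),
       t_recent = c(10, 500), t_deep = c(500, 15000), ra = c(0, 1),
       mu_bar = c(1e-4, 1e-3), p_bar = c(0.1, 0.3))
}

#' Specify a demographic scenario
#'
#' Two historical topologies relate the British population (pop 1), the
#' native Irish sub-population (pop 2) and the British-like Irish
#' sub-population (pop 3).  Under `"divergence"`, pop 3 splits from pop 2
#' at the recent time and pops 1 and 2 split from an ancestral population
#' at the deep time.  Under `"admixture"`, pop 3 is founded at the recent
#' time by admixture drawing a fraction `ra` of its ancestry from pop 1,
#' and pops 1 and 2 split at the deep time.  The ancestral population
#' (before the deep split) takes size `N2` unless overridden.
#'
#' @param topology `"divergence"` or `"admixture"`.
#' @param priors prior bounds as from [default_priors()]; partial lists
#'   override defaults element-wise.
#' @param n_anc ancestral diploid size, or `NULL` to inherit `N2`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(topology = c("divergence", "admixture"),
                          priors = NULL, n_anc = NULL) {
  topology <- match.arg(topology)
  pr <- default_priors()
  if (!is.null(priors)) pr[names(priors)] <- priors
  stopifnot(all(vapply(pr, function(b) length(b) == 2 && b[1] <= b[2] &&
                         b[1] > 0 || identical(b, pr$ra), TRUE)))
  structure(list(topology = topology, priors = pr, n_anc = n_anc,
                 scenario_id = if (topology == "divergence") 1L else 2L),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("scenario_spec:", x$topology, "(scenario", x$scenario_id, ")\n")
  for (nm in names(x$priors))
    cat(sprintf("  %-9s [%g, %g]\n", nm, x$priors[[nm]][1], x$priors[[nm]][2]))
  invisible(x)
}

#' Draw parameter vectors from a scenario's priors
#'
#' Independent uniform draws within the prior bounds; effective sizes and
#' times are drawn as integers (uniform over the bound range); the
#' constraint `t_recent < t_deep` is enforced by redrawing.  Mutation
#' hyper-parameters `mu_bar` and `p_bar` are drawn per dataset; per-locus
#' rates are drawn later (see [draw_locus_rates()]).
#'
#' @param spec a [scenario_spec()].
#' @param n number of draws.
#' @return A data frame with columns `scenario`, `N1`, `N2`, `N3`,
#'   `t_recent`, `t_deep`, `ra` (`NA` for the divergence topology),
#'   `n_anc`, `mu_bar`, `p_bar`.
#' @export
sample_prior <- function(spec, n = 1) {
  pr <- spec$priors
  runif_int <- function(b, n) floor(runif(n, b[1], b[2] + 1))
  N1 <- runif_int(pr$N1, n); N2 <- runif_int(pr$N2, n)
  N3 <- runif_int(pr$N3, n)
  t_recent <- runif_int(pr$t_recent, n)
  t_deep <- runif_int(pr$t_deep, n)
  bad <- which(t_recent >= t_deep)
  while (length(bad)) {
    t_recent[bad] <- runif_int(pr$t_recent, length(bad))
    t_deep[bad] <- runif_int(pr$t_deep, length(bad))
    bad <- bad[t_recent[bad] >= t_deep[bad]]
  }
  ra <- if (spec$topology == "admixture") runif(n, pr$ra[1], pr$ra[2])
        else rep(NA_real_, n)
  data.frame(scenario = spec$scenario_id, N1 = N1, N2 = N2, N3 = N3,
             t_recent = t_recent, t_deep = t_deep, ra = ra,
             n_anc = if (is.null(spec$n_anc)) N2 else spec$n_anc,
             mu_bar = runif(n, pr$mu_bar[1], pr$mu_bar[2]),
             p_bar = runif(n, pr$p_bar[1], pr$p_bar[2]))
}

#' Draw per-locus mutation rates and geometric step parameters
#'
#' Per-locus rates `mu_l ~ Gamma(shape 2, mean mu_bar)` truncated to
#' \[1e-6, 1e-2\] and geometric parameters `P_l ~ Gamma(shape 2, mean
#' p_bar)` truncated to (0.01, 0.9), by redraw.
#'
#' @param mu_bar,p_bar hyper-parameter vectors (one value per dataset).
#' @param n_loci number of loci.
#' @return A list of two matrices `mu` and `P` (datasets x loci).
#' @export
draw_locus_rates <- function(mu_bar, p_bar, n_loci) {
  n <- length(mu_bar)
  draw_trunc <- function(means, lo, hi) {
    x <- rgamma(n * n_loci, shape = 2, rate = 2 / rep(means, n_loci))
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- rgamma(length(bad), shape = 2,
                       rate = 2 / rep(means, n_loci)[bad])
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    matrix(x, n, n_loci)
  }
  list(mu = draw_trunc(mu_bar, 1e-6, 1e-2),
       P = draw_trunc(p_bar, 0.01, 0.9))
}

#' Simulate one microsatellite locus under a demographic scenario
#'
#' Backwards-in-time coalescent over the three sampled populations with a
#' generalized stepwise mutation model: mutations are Poisson on branches
#' with rate `mu` per generation, each moving the allele by a geometrically
#' distributed number of motif steps (parameter `P`; `P = 1` is the strict
#' single-step model), on a bounded 40-state ladder with reflecting
#' boundaries rooted at the ladder midpoint.
#'
#' @param params a one-row data frame as from [sample_prior()] (or a named
#'   list with `N1`, `N2`, `N3`, `t_recent`, `t_deep`, `ra`, `n_anc`).
#' @param scenario 1 (divergence) or 2 (admixture).
#' @param sample_sizes diploid sample sizes of the three populations.
#' @param mu,P per-locus mutation rate and geometric parameter.
#' @param motif repeat motif length in base pairs.
#' @param allele_base allele size (bp) of ladder state 0.
#' @return Integer vector of `2 * sum(sample_sizes)` allele sizes, gene
#'   copies ordered population 1, 2, 3.
#' @export
simulate_locus <- function(params, scenario, sample_sizes, mu, P,
                           motif = 2, allele_base = 100) {
  if (!scenario %in% c(1, 2)) stop("invalid topology: scenario must be 1 or 2")
  if (any(sample_sizes < 1)) stop("sample sizes must be >= 1")
  ra <- if (is.na(params$ra %||% NA)) 0 else params$ra
  .sim_locus_cpp(as.integer(scenario), params$N1, params$N2, params$N3,
                 params$t_recent, params$t_deep, ra,
                 params$n_anc %||% params$N2, mu, P,
                 as.integer(2 * sample_sizes), as.integer(motif),
                 as.integer(allele_base))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full multi-locus genotype table
#'
#' Simulates `n_loci` independent loci under one scenario and packs the
#' gene copies into diploid genotypes (consecutive pairing).
#'
#' @inheritParams simulate_locus
#' @param n_loci number of loci.
#' @param locus_rates optional list with `mu` and `P` vectors (length
#'   `n_loci`); drawn from the hyper-parameters in `params` if omitted.
#' @param population_names labels for the three populations.
#' @return A list with `table` (a [genotype_table()]), `genes` (the loci x
#'   gene-copies allele-size matrix) and `locus_rates`.
#' @export
simulate_genotypes <- function(params, scenario, sample_sizes, n_loci = 14,
                               locus_rates = NULL, motif = 2,
                               allele_base = 100,
                               population_names = c("Pop1", "Pop2", "Pop3")) {
  if (is.null(locus_rates)) {
    lr <- draw_locus_rates(params$mu_bar, params$p_bar, n_loci)
    locus_rates <- list(mu = lr$mu[1, ], P = lr$P[1, ])
  }
  ra <- if (is.na(params$ra %||% NA)) 0 else params$ra
  genes <- .simulate_genes_cpp(as.integer(scenario),
                               c(params$N1, params$N2, params$N3,
                                 params$t_recent, params$t_deep, ra,
                                 params$n_anc %||% params$N2),
                               locus_rates$mu, locus_rates$P,
                               as.integer(2 * sample_sizes),
                               as.integer(motif), as.integer(allele_base))
  n_ind <- sum(sample_sizes)
  a1 <- t(genes[, 2 * seq_len(n_ind) - 1, drop = FALSE])
  a2 <- t(genes[, 2 * seq_len(n_ind), drop = FALSE])
  pops <- rep(population_names, sample_sizes)
  ids <- paste0(rep(population_names, sample_sizes), "_",
                unlist(lapply(sample_sizes, seq_len)))
  tab <- genotype_table(a1, a2, ids, paste0("L", seq_len(n_loci)), pops)
  list(table = tab, genes = genes, locus_rates = locus_rates)
}

#' Simulate summary vectors for a set of parameter draws
#'
#' The fast path behind the reference table: for each draw, simulates
#' `n_loci` loci and computes the 15-statistic summary vector (see
#' [summary_names()]) directly.
#'
#' @param draws a data frame as from [sample_prior()] (any number of rows).
#' @param sample_sizes diploid sample sizes of the three populations.
#' @param n_loci number of loci.
#' @param motif,allele_base see [simulate_locus()].
#' @return A numeric matrix (draws x 15) with columns [summary_names()].
#' @export
simulate_summaries <- function(draws, sample_sizes, n_loci = 14,
                               motif = 2, allele_base = 100) {
  lr <- draw_locus_rates(draws$mu_bar, draws$p_bar, n_loci)
  ra <- ifelse(is.na(draws$ra), 0, draws$ra)
  demog <- cbind(draws$N1, draws$N2, draws$N3, draws$t_recent,
                 draws$t_deep, ra, draws$n_anc)
  out <- .simulate_summaries_cpp(as.integer(draws$scenario), demog,
                                 lr$mu, lr$P, as.integer(2 * sample_sizes),
                                 as.integer(motif), as.integer(allele_base))
  colnames(out) <- summary_names()
  out
}

#' Build an ABC reference table
#'
#' Prior-predictive simulation: for each scenario, draws parameters from
#' the priors and simulates multi-locus datasets, recording
#' (scenario, parameters, summary statistics) per row.  Work proceeds in
#' chunks with per-chunk seeds derived deterministically from `seed`
#' (`chunk_seed = (seed + 1000003 * chunk) mod 2^31 - 1`), so the table is
#' reproducible, chunk-order invariant, and resumable: if `path` is given,
#' each completed chunk is appended to the tab-delimited file and a
#' partially written table is completed rather than restarted.
#'
#' @param specs list of [scenario_spec()] objects (typically both
#'   topologies).
#' @param n_per_scenario simulated datasets per scenario (>= 100).
#' @param sample_sizes diploid sample sizes of the three populations.
#' @param n_loci number of loci.
#' @param seed master seed.
#' @param chunk_size draws per chunk.
#' @param path optional file to persist/resume the table.
#' @param motif,allele_base see [simulate_locus()].
#' @return A data frame: `scenario`, the parameter columns of
#'   [sample_prior()], and the 15 summary columns of [summary_names()].
#' @export
build_reference_table <- function(specs, n_per_scenario, sample_sizes,
                                  n_loci = 14, seed = 1, chunk_size = 1000,
                                  path = NULL, motif = 2, allele_base = 100) {
  if (n_per_scenario < 100) stop("n_per_scenario must be >= 100")
  plan <- list()
  for (s in seq_along(specs)) {
    n_chunks <- ceiling(n_per_scenario / chunk_size)
    sizes <- rep(chunk_size, n_chunks)
    sizes[n_chunks] <- n_per_scenario - chunk_size * (n_chunks - 1)
    for (k in seq_len(n_chunks))
      plan[[length(plan) + 1]] <- list(spec = specs[[s]], n = sizes[k],
                                       chunk = length(plan) + 1)
  }
  done_rows <- 0
  if (!is.null(path) && file.exists(path)) {
    prev <- read.table(path, header = TRUE, sep = "\t")
    done_rows <- nrow(prev)
  }
  chunks <- list()
  rows_seen <- 0
  for (item in plan) {
    if (rows_seen + item$n <= done_rows) {
      rows_seen <- rows_seen + item$n
      next  # chunk already persisted
    }
    set.seed((seed + 1000003 * item$chunk) %% (2^31 - 1))
    draws <- sample_prior(item$spec, item$n)
    summ <- simulate_summaries(draws, sample_sizes, n_loci,
                               motif = motif, allele_base = allele_base)
    chunk <- cbind(draws, as.data.frame(summ))
    if (!is.null(path)) {
      write.table(chunk, path, sep = "\t", row.names = FALSE,
                  col.names = !file.exists(path), append = file.exists(path))
    }
    chunks[[length(chunks) + 1]] <- chunk
    rows_seen <- rows_seen + item$n
  }
  if (!is.null(path)) {
    out <- read.table(path, header = TRUE, sep = "\t")
  } else {
    out <- do.call(rbind, chunks)
  }
  rownames(out) <- NULL
  out
}
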