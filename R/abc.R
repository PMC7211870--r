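#' Names and order of the summary-statistic vector
#'
#' The fixed 15-statistic layout shared by observed and simulated data:
#' per population (1 = British, 2 = native Irish, 3 = British-like Irish)
#' the across-locus mean allele number, mean genic diversity (Nei unbiased)
#' and mean Garza-Williamson M-ratio; then pairwise Weir-Cockerham
#' \eqn{\theta} and delta-mu-squared for the population pairs (1,2), (1,3),
#' (2,3).
#'
#' @return Character vector of 15 names.
#' @export
summary_names <- function() {
  c(paste0("na_", 1:3), paste0("he_", 1:3), paste0("m_", 1:3),
    paste0("fst_", c("12", "13", "23")), paste0("dmu2_", c("12", "13", "23")))
}

#' Compute the observed summary vector from a genotype table
#'
#' Same statistic definitions, estimators and ordering as the simulated
#' summaries, so observed and reference-table rows are directly comparable.
#' A dataset simulated by [simulate_genotypes()] and fed back through this
#' function reproduces the summary vector stored during simulation.
#'
#' @param table a [genotype_table()].
#' @param population_labels the three population labels, in the order
#'   (British, native Irish, British-like Irish).
#' @param motif repeat motif length in base pairs.
#' @return Named numeric vector of length 15 ([summary_names()]).  With a
#'   fully monomorphic dataset the diversity statistics are 0, M-ratios 1,
#'   and the uninformative \eqn{\theta} values are flagged by attribute
#'   `fst_undefined`.
#' @export
compute_observed_summaries <- function(table, population_labels, motif = 2) {
  if (length(population_labels) != 3)
    stop("exactly three population labels required")
  missing_pops <- setdiff(population_labels, populations(table))
  if (length(missing_pops))
    stop("population not in table: ", paste(missing_pops, collapse = ", "))
  out <- setNames(numeric(15), summary_names())
  for (p in 1:3) {
    freqs <- allele_frequencies(table, population_labels[p])
    informative <- vapply(freqs, function(f) f$n_genes > 0, TRUE)
    out[p] <- mean(vapply(freqs[informative],
                          function(f) length(f$allele_counts), 0))
    out[3 + p] <- mean(vapply(freqs[informative], function(f)
      unbiased_gene_diversity(f$allele_counts, f$n_genes), 0))
    out[6 + p] <- mean(vapply(freqs[informative], m_ratio, 0,
                              motif_length = motif))
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  undefined <- character(0)
  for (q in 1:3) {
    A <- population_labels[pairs[[q]][1]]; B <- population_labels[pairs[[q]][2]]
    th <- pairwise_fst(table, A, B)$theta
    if (is.na(th)) { undefined <- c(undefined, names(out)[9 + q]); th <- 0 }
    out[9 + q] <- th
    out[12 + q] <- delta_mu_squared(table, A, B, motif_length = motif)$delta_mu_sq
  }
  if (length(undefined)) attr(out, "fst_undefined") <- undefined
  out
}

#' ABC rejection step
#'
#' Standardizes every summary column by its reference-table standard
#' deviation (or median absolute deviation), computes Euclidean distances
#' between each reference row and the observed vector, and keeps the
#' closest `ceiling(tolerance * n)` rows; ties at the cutoff are broken by
#' row order.  Zero-variance columns are dropped from the distance with a
#' warning.
#'
#' @param ref reference table from [build_reference_table()].
#' @param observed named summary vector ([compute_observed_summaries()]).
#' @param tolerance fraction of rows to accept, in (0, 1].
#' @param scale `"sd"` (default) or `"mad"` column standardization.
#' @return A list: `accepted` (the accepted rows of `ref`), `distances`
#'   (their distances, ascending with row order preserved), `indices`,
#'   `cutoff`, `dropped_columns`.
#' @export
abc_rejection <- function(ref, observed, tolerance = 0.01,
                          scale = c("sd", "mad")) {
  scale <- match.arg(scale)
  if (nrow(ref) == 0) stop("empty reference table")
  if (!(tolerance > 0 && tolerance <= 1)) stop("tolerance must be in (0, 1]")
  cols <- intersect(summary_names(), colnames(ref))
  S <- as.matrix(ref[, cols, drop = FALSE])
  obs <- observed[cols]
  sds <- apply(S, 2, if (scale == "sd") sd else stats::mad)
  dropped <- cols[!is.finite(sds) | sds == 0]
  if (length(dropped))
    warning("zero-variance summary columns dropped from distance: ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(cols, dropped)
  Z <- sweep(S[, keep, drop = FALSE], 2, sds[keep], "/")
  zobs <- obs[keep] / sds[keep]
  d <- sqrt(rowSums(sweep(Z, 2, zobs)^2))
  n_keep <- ceiling(tolerance * nrow(ref))
  ord <- order(d)  # stable: ties broken by row order
  idx <- sort(ord[seq_len(n_keep)])
  list(accepted = ref[idx, , drop = FALSE], distances = d[idx],
       indices = idx, cutoff = max(d[idx]), dropped_columns = dropped,
       all_distances = d)
}

epanechnikov <- function(d, bandwidth) {
  u <- d / bandwidth
  w <- 1 - u^2
  w[u > 1] <- 0
  w
}

#' Scenario posterior probabilities by weighted logistic regression
#'
#' Among the accepted rows, regresses the scenario indicator on the
#' centred summaries (summary minus observed) with Epanechnikov weights in
#' distance (bandwidth = the maximum accepted distance) and evaluates the
#' fit at the origin, i.e. at the observed data.  The 95% CI comes from
#' the delta-method standard error of the linear predictor at the origin,
#' mapped through the inverse logit.
#'
#' @param accepted accepted rows ([abc_rejection()]`$accepted`).
#' @param distances their distances.
#' @param observed the observed summary vector.
#' @return A data frame with one row per scenario: `scenario`,
#'   `posterior`, `lower`, `upper` (probabilities sum to 1).  If only one
#'   scenario survives rejection its probability is 1 with a degenerate CI
#'   and a warning.
#' @export
scenario_posterior <- function(accepted, distances, observed) {
  scen <- sort(unique(accepted$scenario))
  if (length(scen) == 1) {
    warning("all accepted rows are from scenario ", scen,
            "; posterior is degenerate")
    out <- data.frame(scenario = c(1, 2), posterior = c(0, 0),
                      lower = c(0, 0), upper = c(0, 0))
    out[out$scenario == scen, c("posterior", "lower", "upper")] <- 1
    return(out)
  }
  cols <- intersect(summary_names(), colnames(accepted))
  X <- sweep(as.matrix(accepted[, cols, drop = FALSE]), 2, observed[cols])
  # drop columns with no variation among accepted rows
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  w <- epanechnikov(distances, max(distances))
  w[w == 0] <- min(w[w > 0]) / 2  # keep boundary rows in the fit
  df <- data.frame(y = as.integer(accepted$scenario == 2), X)
  fit <- suppressWarnings(
    glm(y ~ ., data = df, family = binomial(), weights = w))
  pr <- predict(fit, newdata = as.data.frame(t(setNames(
    rep(0, ncol(X)), colnames(X)))), type = "link", se.fit = TRUE)
  p2 <- plogis(pr$fit)
  lo2 <- plogis(pr$fit - 1.96 * pr$se.fit)
  hi2 <- plogis(pr$fit + 1.96 * pr$se.fit)
  data.frame(scenario = c(1, 2),
             posterior = c(1 - p2, p2),
             lower = c(1 - hi2, lo2), upper = c(1 - lo2, hi2))
}

# logit transform of x onto its prior interval and back
to_bounded_logit <- function(x, bounds) {
  u <- (x - bounds[1]) / (bounds[2] - bounds[1])
  u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
  qlogis(u)
}
from_bounded_logit <- function(y, bounds) {
  bounds[1] + plogis(y) * (bounds[2] - bounds[1])
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' Parameter posteriors by local-linear regression adjustment
#'
#' Beaumont-style ABC regression for the accepted rows of one scenario:
#' each parameter is mapped onto its prior interval by a bounded logit
#' transform, regressed on the centred summaries with Epanechnikov
#' weights, adjusted to the origin
#' (\eqn{\theta^*_i = \theta_i - b'(S_i - S_{obs})}), back-transformed,
#' and summarized by the weighted mean, median and 2.5%/97.5% quantiles.
#' A singular regression falls back to unadjusted weighted quantiles with
#' a warning.
#'
#' @param accepted accepted rows of the winning scenario (>= 50).
#' @param distances their distances.
#' @param observed the observed summary vector.
#' @param priors named list of prior bounds ([default_priors()]) for the
#'   parameters to summarize.
#' @param parameters parameter column names; defaults to the demographic
#'   parameters present and applicable.
#' @return A list with `summary` (data frame: `parameter`, `mean`,
#'   `median`, `q025`, `q975`), `sample` (matrix of adjusted posterior
#'   draws), `weights`.
#' @export
parameter_posterior <- function(accepted, distances, observed,
                                priors = default_priors(),
                                parameters = NULL) {
  if (nrow(accepted) < 50)
    stop("need >= 50 accepted rows for parameter estimation, have ",
         nrow(accepted))
  if (is.null(parameters)) {
    parameters <- intersect(c("N1", "N2", "N3", "t_recent", "t_deep", "ra"),
                            colnames(accepted))
    parameters <- parameters[vapply(parameters, function(p)
      !anyNA(accepted[[p]]), TRUE)]
  }
  cols <- intersect(summary_names(), colnames(accepted))
  X <- sweep(as.matrix(accepted[, cols, drop = FALSE]), 2, observed[cols])
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  w <- epanechnikov(distances, max(distances))
  w[w == 0] <- min(w[w > 0]) / 2
  adj <- matrix(NA_real_, nrow(accepted), length(parameters),
                dimnames = list(NULL, parameters))
  for (p in parameters) {
    bounds <- priors[[p]]
    if (is.null(bounds))
      bounds <- range(accepted[[p]]) + c(-1, 1) * 1e-8
    y <- to_bounded_logit(accepted[[p]], bounds)
    fit <- tryCatch(lm.wfit(cbind(1, X), y, w), error = function(e) NULL)
    if (is.null(fit) || all(is.na(fit$coefficients[-1]))) {
      warning("singular regression for ", p,
              "; falling back to unadjusted weighted quantiles")
      ystar <- y
    } else {
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      ystar <- y - drop(X %*% beta)
    }
    adj[, p] <- from_bounded_logit(ystar, bounds)
  }
  summ <- do.call(rbind, lapply(parameters, function(p) {
    q <- weighted_quantile(adj[, p], w, c(0.025, 0.5, 0.975))
    data.frame(parameter = p,
               mean = sum(w * adj[, p]) / sum(w),
               median = q[2], q025 = q[1], q975 = q[3])
  }))
  rownames(summ) <- NULL
  list(summary = summ, sample = adj, weights = w)
}

#' Convert generations to years
#'
#' @param g time in generations before present (non-negative).
#' @param generation_time_years badger generation time in years (default 6).
#' @return Time in years before present.
#' @examples
#' generations_to_years(110)   # 660
#' generations_to_years(1820)  # 10920
#' @export
generations_to_years <- function(g, generation_time_years = 6) {
  if (any(g < 0)) stop("generations must be non-negative")
  g * generation_time_years
}

#' PCA model check of simulated against observed summaries
#'
#' Fits principal components on the standardized prior-predictive
#' summaries, projects prior, posterior-predictive and observed points,
#' and reports whether the observed point lies within the central 95% of
#' the posterior-predictive cloud (squared Mahalanobis distance in the
#' leading PC space against the chi-squared 0.95 quantile).
#'
#' @param prior_summaries matrix of prior-predictive summary vectors
#'   (>= 100 rows).
#' @param posterior_summaries matrix of posterior-predictive summary
#'   vectors (>= 50 rows).
#' @param observed the observed summary vector.
#' @param n_pc number of leading components used for the distance.
#' @return A list: `prior_coords`, `posterior_coords`, `observed_coords`
#'   (2-D projections), `inside` (logical), `mahalanobis_sq`, `threshold`,
#'   `rotation`.
#' @export
pca_model_check <- function(prior_summaries, posterior_summaries, observed,
                            n_pc = 5) {
  if (nrow(prior_summaries) < 100) stop("need >= 100 prior rows")
  if (nrow(posterior_summaries) < 50) stop("need >= 50 posterior rows")
  cols <- colnames(prior_summaries)
  sds <- apply(prior_summaries, 2, sd)
  keep <- which(is.finite(sds) & sds > 0)
  ctr <- colMeans(prior_summaries[, keep, drop = FALSE])
  pca <- prcomp(prior_summaries[, keep, drop = FALSE],
                center = TRUE, scale. = TRUE)
  proj <- function(M) {
    Z <- sweep(sweep(M[, keep, drop = FALSE], 2, pca$center), 2,
               pca$scale, "/")
    Z %*% pca$rotation
  }
  pp <- proj(posterior_summaries)
  op <- proj(matrix(observed[cols], 1, dimnames = list(NULL, cols)))
  k <- min(n_pc, ncol(pp), nrow(posterior_summaries) - 1)
  m2 <- mahalanobis(op[, seq_len(k), drop = FALSE],
                    colMeans(pp[, seq_len(k), drop = FALSE]),
                    cov(pp[, seq_len(k), drop = FALSE]))
  thr <- qchisq(0.95, df = k)
  list(prior_coords = proj(prior_summaries)[, 1:2, drop = FALSE],
       posterior_coords = pp[, 1:2, drop = FALSE],
       observed_coords = op[, 1:2, drop = FALSE],
       inside = as.logical(m2 <= thr),
       mahalanobis_sq = as.numeric(m2), threshold = thr,
       rotation = pca$rotation)
}
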