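#' Read a clustering log-likelihood table
#'
#' Delimited text with columns `K`, `replicate` (optional) and `lnP`
#' (aliases `lnp`, `ln_prob`, `est_ln_prob` accepted, case-insensitive).
#' Without a replicate column, replicates are numbered within each K in
#' file order.
#'
#' @param path path to a delimited file with a header row.
#' @return A data frame with columns `K`, `replicate`, `lnP`.
#' @export
read_loglik_table <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  lnp_col <- intersect(c("lnp", "ln_prob", "est_ln_prob", "lnlik"), names(df))
  if (!"k" %in% names(df) || length(lnp_col) == 0)
    stop("log-likelihood table needs columns K and lnP")
  out <- data.frame(K = as.integer(df$k), lnP = as.numeric(df[[lnp_col[1]]]))
  out$replicate <- if ("replicate" %in% names(df)) as.integer(df$replicate)
                   else stats::ave(out$K, out$K, FUN = seq_along)
  out[c("K", "replicate", "lnP")]
}

#' Evanno delta-K from replicated clustering log-likelihoods
#'
#' For each interior K,
#' \eqn{\Delta K = \mathrm{mean}_r |L_r(K+1) - 2 L_r(K) + L_r(K-1)| /
#' \mathrm{sd}_r L_r(K)}: the mean over replicates of the absolute second
#' difference of the log-likelihood, divided by the standard deviation of
#' the replicate likelihoods at K.  Replicates are paired by replicate
#' index when counts match across K, otherwise the second difference of
#' the per-K means is used.  Endpoints are undefined; a zero standard
#' deviation leaves that K undefined and flagged.
#'
#' @param tbl a data frame with columns `K`, `replicate`, `lnP` (e.g. from
#'   [read_loglik_table()]).  At least 3 consecutive K values with >= 2
#'   replicates each.
#' @return A data frame with columns `K`, `mean_lnP`, `sd_lnP`, `delta_K`,
#'   `flagged` (TRUE where sd is zero).  `delta_K` is invariant to adding
#'   a constant to all `lnP`.
#' @export
evanno_delta_k <- function(tbl) {
  ks <- sort(unique(tbl$K))
  if (length(ks) < 3 || any(diff(ks) != 1))
    stop("need >= 3 consecutive K values")
  reps <- table(tbl$K)
  if (any(reps < 2)) stop("need >= 2 replicates per K")
  by_k <- lapply(ks, function(k) {
    sub <- tbl[tbl$K == k, ]
    sub$lnP[order(sub$replicate)]
  })
  names(by_k) <- ks
  paired <- length(unique(lengths(by_k))) == 1
  out <- data.frame(K = ks,
                    mean_lnP = vapply(by_k, mean, 0),
                    sd_lnP = vapply(by_k, sd, 0),
                    delta_K = NA_real_, flagged = FALSE)
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    if (out$sd_lnP[i] == 0) { out$flagged[i] <- TRUE; next }
    second_diff <- if (paired)
      mean(abs(by_k[[i + 1]] - 2 * by_k[[i]] + by_k[[i - 1]]))
    else
      abs(out$mean_lnP[i + 1] - 2 * out$mean_lnP[i] + out$mean_lnP[i - 1])
    out$delta_K[i] <- second_diff / out$sd_lnP[i]
  }
  rownames(out) <- NULL
  out
}

#' Read a cluster-membership (Q) matrix
#'
#' Accepts either delimited text with an `id` column followed by one
#' column per cluster, or a raw STRUCTURE output file containing an
#' "Inferred ancestry of individuals" block with lines of the form
#' `n id (miss) pop : q1 q2 ...`.
#'
#' @param path input file path.
#' @return A data frame with column `id` followed by numeric cluster
#'   columns `Q1`, `Q2`, ...
#' @export
read_qmatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  anc <- grep("Inferred ancestry of individuals", lines)
  if (length(anc)) {
    block <- lines[-seq_len(anc)]
    block <- block[grepl(":", block)]
    rows <- lapply(block, function(ln) {
      halves <- strsplit(ln, ":", fixed = TRUE)[[1]]
      left <- strsplit(trimws(halves[1]), "[[:space:]]+")[[1]]
      q <- suppressWarnings(
        as.numeric(strsplit(trimws(halves[2]), "[[:space:]]+")[[1]]))
      if (length(q) == 0 || anyNA(q)) return(NULL)  # e.g. the column header
      data.frame(id = left[2], t(q))
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no Q rows found in ", path)
  } else {
    header <- lines[1]
    sep <- if (grepl("\t", header)) "\t" else ","
    out <- read.table(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE)
    names(out)[1] <- "id"
  }
  names(out) <- c("id", paste0("Q", seq_len(ncol(out) - 1)))
  out$id <- as.character(out$id)
  out
}

#' Partition individuals by a cluster-membership threshold
#'
#' Individuals whose membership in the reference cluster is at least the
#' threshold form the "native" group; the rest (more than
#' `1 - threshold` foreign heritage) form the "admixed" group.  Raising
#' the threshold never grows the native group.
#'
#' @param q a Q-matrix data frame from [read_qmatrix()].
#' @param reference_cluster the column (index or name like `"Q1"`) holding
#'   the native-cluster membership.
#' @param threshold Q-score threshold, default 0.85 (inclusive).
#' @return A data frame with columns `id`, `Q`, `group` (`"native"` or
#'   `"admixed"`).
#' @export
q_threshold_partition <- function(q, reference_cluster = 1,
                                  threshold = 0.85) {
  qcols <- grep("^Q", names(q), value = TRUE)
  qm <- as.matrix(q[, qcols, drop = FALSE])
  bad <- abs(rowSums(qm) - 1) > 1e-6
  if (any(bad))
    stop("Q rows do not sum to 1 for: ",
         paste(q$id[bad], collapse = ", "))
  ref <- if (is.character(reference_cluster)) q[[reference_cluster]]
         else qm[, reference_cluster]
  data.frame(id = q$id, Q = ref,
             group = ifelse(ref >= threshold, "native", "admixed"))
}
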