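#' Mitochondrial sequence diversity summaries per group
#'
#' For aligned equal-length control-region sequences partitioned into
#' groups, reports per group the number of distinct haplotypes, the number
#' of segregating sites, and the mean and variance of pairwise nucleotide
#' differences; plus, for every pair of groups, a sequence
#' \eqn{F_{ST} = 1 - \bar\pi_{within} / \bar\pi_{between}} (Hudson's
#' within/between formulation, with \eqn{\bar\pi_{within}} the unweighted
#' mean of the two groups' mean pairwise differences).
#'
#' Pairwise differences are counted over sites where neither sequence is
#' ambiguous (pairwise deletion of `N`/gap sites).
#'
#' @param seqs named character vector of aligned sequences.
#' @param partition character or factor of group labels, one per sequence
#'   (recycled names are matched by position).
#' @return A list with `per_group` (data frame: `group`, `n`,
#'   `n_haplotypes`, `segregating_sites`, `mean_pairwise_diff`,
#'   `var_pairwise_diff`) and `pairwise_fst` (data frame: `groupA`,
#'   `groupB`, `fst`).
#' @export
mtdna_summaries <- function(seqs, partition) {
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences are not aligned to equal length")
  if (length(partition) != length(seqs))
    stop("partition must label every sequence")
  partition <- as.character(partition)
  mat <- do.call(rbind, strsplit(tolower(seqs), ""))
  dna <- ape::as.DNAbin(mat)
  d <- as.matrix(ape::dist.dna(dna, model = "N", pairwise.deletion = TRUE))
  groups <- unique(partition)

  group_pairs <- function(idx) {
    if (length(idx) < 2) return(numeric(0))
    d[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
  }
  per_group <- do.call(rbind, lapply(groups, function(g) {
    idx <- which(partition == g)
    ss <- segregating_sites(mat[idx, , drop = FALSE])
    pw <- group_pairs(idx)
    data.frame(group = g, n = length(idx),
               n_haplotypes = length(unique(toupper(seqs[idx]))),
               segregating_sites = ss,
               mean_pairwise_diff = if (length(pw)) mean(pw) else 0,
               var_pairwise_diff = if (length(pw) > 1) var(pw) else 0)
  }))
  rownames(per_group) <- NULL

  fst_rows <- list()
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) for (j in seq(i + 1, length(groups))) {
      ia <- which(partition == groups[i]); ib <- which(partition == groups[j])
      within <- mean(c(mean(group_pairs(ia)), mean(group_pairs(ib))), na.rm = TRUE)
      between <- mean(d[ia, ib])
      fst <- if (between > 0) 1 - within / between else 0
      fst_rows[[length(fst_rows) + 1]] <-
        data.frame(groupA = groups[i], groupB = groups[j], fst = fst)
    }
  }
  list(per_group = per_group,
       pairwise_fst = if (length(fst_rows)) do.call(rbind, fst_rows)
                      else data.frame(groupA = character(0),
                                      groupB = character(0), fst = numeric(0)))
}

# number of alignment columns with more than one distinct unambiguous base
segregating_sites <- function(mat) {
  bases <- c("a", "c", "g", "t")
  sum(apply(mat, 2, function(col) {
    col <- col[col %in% bases]
    length(unique(col)) > 1
  }))
}
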