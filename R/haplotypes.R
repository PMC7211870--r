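#' Build and validate a haplotype catalogue
#'
#' A catalogue maps haplotype names (H1, H2, ...) to equal-length reference
#' control-region sequences.
#'
#' @param seqs named character vector of reference sequences.
#' @return The validated named character vector, class `haplotype_catalogue`.
#' @export
haplotype_catalogue <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("catalogue sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1)
    stop("catalogue sequences must be of equal length")
  structure(toupper(seqs), class = "haplotype_catalogue")
}

#' Read a haplotype catalogue from FASTA
#' @param path path to a FASTA file of named reference sequences.
#' @return A [haplotype_catalogue()].
#' @export
read_haplotype_catalogue <- function(path) haplotype_catalogue(read_fasta(path))

#' Synthetic control-region haplotype catalogue
#'
#' A stand-in for the published reference haplotypes, which are not
#' redistributed here: seven named 214 bp sequences (H1, H2, H4, H9, H14,
#' H15, H20) derived from one fixed synthetic backbone by substitutions at
#' fixed positions.  As in the real catalogue, H20 differs from H9 at
#' exactly one position.  The catalogue is deterministic (no RNG) so
#' haplotype assignment against it is reproducible.
#'
#' @return A [haplotype_catalogue()] of 7 sequences.
#' @examples
#' cat214 <- synthetic_haplotype_catalogue()
#' nchar(cat214[["H9"]])
#' @export
synthetic_haplotype_catalogue <- function() {
  backbone <- paste0(
    "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA",
    "CGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC",
    "AACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCT",
    "CGTG")
  # transversion map guarantees every listed position really changes
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  sub_at <- function(s, pos) {
    for (p in pos) substr(s, p, p) <- flip[[substr(s, p, p)]]
    s
  }
  # each haplotype is the backbone flipped at a fixed position set;
  # H20 = H9 plus one extra substitution (position 160)
  h9 <- sub_at(backbone, c(12, 45, 101))
  haplotype_catalogue(c(
    H1  = sub_at(backbone, c(20, 77, 130, 190)),
    H2  = sub_at(backbone, c(33, 88, 140)),
    H4  = sub_at(backbone, c(20, 77, 150)),
    H9  = h9,
    H14 = sub_at(backbone, c(5, 60, 170, 205)),
    H15 = sub_at(backbone, c(12, 95, 180)),
    H20 = sub_at(h9, 160)))
}

#' Assign sequences to named haplotypes
#'
#' Exact-match assignment against a reference catalogue: a sequence whose
#' informative (non-`N`) sites all agree with a reference takes that
#' reference's name with 0 mismatches; otherwise the sequence is `NOVEL`,
#' reported with its nearest reference and the Hamming distance to it
#' (`N` sites excluded).  Ties for the nearest reference are broken by
#' catalogue order and flagged as ambiguous.  Sequences longer than the
#' references are trimmed by sliding the reference window over the read and
#' keeping the best-matching (end-anchored) offset.
#'
#' @param seqs named character vector of query sequences.
#' @param catalogue a [haplotype_catalogue()].
#' @return A data frame with columns `individual_id`, `haplotype` (a
#'   catalogue name or `"NOVEL"`), `nearest`, `mismatches`, `ambiguous`.
#' @export
assign_haplotypes <- function(seqs, catalogue) {
  ref_len <- nchar(catalogue[[1]])
  ref_mat <- do.call(rbind, strsplit(unname(toupper(catalogue)), ""))
  rows <- lapply(seq_along(seqs), function(i) {
    s <- toupper(seqs[[i]])
    if (nchar(s) < ref_len)
      stop("sequence ", names(seqs)[i], " shorter than catalogue references")
    if (nchar(s) > ref_len) s <- trim_to_reference(s, catalogue[[1]], ref_len)
    q <- strsplit(s, "")[[1]]
    informative <- q %in% c("A", "C", "G", "T")
    if (!any(informative))
      stop("sequence ", names(seqs)[i], " is uninformative (all N)")
    dists <- vapply(seq_len(nrow(ref_mat)), function(r) {
      sum(q[informative] != ref_mat[r, informative])
    }, 0L)
    best <- which(dists == min(dists))
    data.frame(individual_id = names(seqs)[i],
               haplotype = if (dists[best[1]] == 0L)
                 names(catalogue)[best[1]] else "NOVEL",
               nearest = names(catalogue)[best[1]],
               mismatches = dists[best[1]],
               ambiguous = length(best) > 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# keep the window of `s` (length ref_len) closest to the reference,
# preferring end-anchored offsets (first and last windows tried first)
trim_to_reference <- function(s, ref, ref_len) {
  offsets <- 0:(nchar(s) - ref_len)
  offsets <- unique(c(0, max(offsets), offsets))
  r <- strsplit(toupper(ref), "")[[1]]
  best <- NULL; best_d <- Inf
  for (off in offsets) {
    w <- substr(s, off + 1, off + ref_len)
    q <- strsplit(w, "")[[1]]
    ok <- q %in% c("A", "C", "G", "T")
    d <- sum(q[ok] != r[ok])
    if (d < best_d) { best_d <- d; best <- w }
  }
  best
}

#' Haplotype frequencies per group
#'
#' Percentages of each assigned haplotype within each group, over assigned
#' individuals.
#'
#' @param assignments output of [assign_haplotypes()], or any data frame
#'   with columns `individual_id` and `haplotype`.
#' @param partition character vector of group labels, one per assignment
#'   row.
#' @return A data frame with columns `group`, `haplotype`, `count`,
#'   `percent` (exact) and `percent_1dp` (rounded to 1 decimal).  Within
#'   each group, exact percentages sum to 100.
#' @export
haplotype_frequencies <- function(assignments, partition) {
  if (nrow(assignments) == 0) stop("empty assignment table")
  if (length(partition) != nrow(assignments))
    stop("partition must label every assignment")
  partition <- as.character(partition)
  rows <- list()
  for (g in unique(partition)) {
    hap <- assignments$haplotype[partition == g]
    if (length(hap) == 0) stop("empty group: ", g)
    tab <- sort(table(hap), decreasing = TRUE)
    rows[[length(rows) + 1]] <-
      data.frame(group = g, haplotype = names(tab),
                 count = as.integer(tab),
                 percent = 100 * as.integer(tab) / length(hap))
  }
  out <- do.call(rbind, rows)
  out$percent_1dp <- round(out$percent, 1)
  rownames(out) <- NULL
  out
}
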