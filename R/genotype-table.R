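#' Diploid microsatellite genotype table
#'
#' The central container for multi-locus diploid genotypes: a set of
#' individuals, each carrying an unordered pair of integer allele sizes
#' (fragment sizes in base pairs, or any integer coding) at each locus, plus
#' a population label per individual.  Missing genotypes are `NA` in both
#' allele slots.
#'
#' @param allele1,allele2 integer matrices (individuals x loci) holding the
#'   two allele sizes per genotype; `NA` marks a missing genotype.  The pair
#'   is unordered and is stored with `allele1 <= allele2`.
#' @param individual_ids character vector of unique individual identifiers.
#' @param locus_names character vector of unique locus names.
#' @param population_labels character vector, one population label per
#'   individual.
#' @return An object of class `genotype_table` with elements `allele1`,
#'   `allele2`, `individual_ids`, `locus_names`, `population_labels`.
#' @examples
#' gt <- genotype_table(matrix(c(10L, 10L), 2, 1), matrix(c(10L, 12L), 2, 1),
#'                      c("b1", "b2"), "Mel101", c("GB", "GB"))
#' populations(gt)
#' @export
genotype_table <- function(allele1, allele2, individual_ids, locus_names,
                           population_labels) {
  allele1 <- as.matrix(allele1); allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"; storage.mode(allele2) <- "integer"
  n <- length(individual_ids)
  if (nrow(allele1) != n || nrow(allele2) != n)
    stop("allele matrices must have one row per individual")
  if (ncol(allele1) != length(locus_names) ||
      ncol(allele2) != length(locus_names))
    stop("allele matrices must have one column per locus")
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_names)) stop("duplicate locus names")
  if (length(population_labels) != n)
    stop("need one population label per individual")
  if (any(xor(is.na(allele1), is.na(allele2))))
    stop("half-missing genotypes are not representable; set both alleles NA")
  if (any(allele1 < 0, na.rm = TRUE) || any(allele2 < 0, na.rm = TRUE))
    stop("allele sizes must be non-negative integers")
  # store the unordered pair in sorted order
  swap <- !is.na(allele1) & allele1 > allele2
  if (any(swap)) {
    tmp <- allele1[swap]
    allele1[swap] <- allele2[swap]
    allele2[swap] <- tmp
  }
  dimnames(allele1) <- dimnames(allele2) <-
    list(individual_ids, locus_names)
  structure(list(allele1 = allele1, allele2 = allele2,
                 individual_ids = as.character(individual_ids),
                 locus_names = as.character(locus_names),
                 population_labels = as.character(population_labels)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individual_ids), "individuals x",
      length(x$locus_names), "loci\n")
  tab <- table(x$population_labels)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Population labels present in a genotype table
#' @param table a [genotype_table()].
#' @return Character vector of unique population labels, in order of first
#'   appearance.
#' @export
populations <- function(table) unique(table$population_labels)

#' Subset a genotype table to one population
#' @param table a [genotype_table()].
#' @param population a population label present in `table`.
#' @return A `genotype_table` restricted to that population's individuals.
#' @export
subset_population <- function(table, population) {
  keep <- table$population_labels %in% population
  if (!any(keep)) stop("population not found: ", population)
  genotype_table(table$allele1[keep, , drop = FALSE],
                 table$allele2[keep, , drop = FALSE],
                 table$individual_ids[keep], table$locus_names,
                 table$population_labels[keep])
}

#' Convert a delimited genotype data frame to a genotype table
#'
#' Converter hook for supplementary-style layouts: a data frame with an id
#' column, a population column, and one column per locus holding genotypes
#' coded as `"a/b"` (or with a custom separator).  Blank or `NA` cells are
#' missing genotypes.
#'
#' @param df a data frame.
#' @param id_col,pop_col names of the identifier and population columns.
#' @param locus_cols names of the genotype columns; defaults to every other
#'   column.
#' @param sep separator between the two alleles within a cell.
#' @return A [genotype_table()].
#' @export
as_genotype_table <- function(df, id_col = "id", pop_col = "population",
                              locus_cols = NULL, sep = "/") {
  if (!all(c(id_col, pop_col) %in% names(df)))
    stop("data frame lacks columns: ",
         paste(setdiff(c(id_col, pop_col), names(df)), collapse = ", "))
  if (is.null(locus_cols)) locus_cols <- setdiff(names(df), c(id_col, pop_col))
  n <- nrow(df); L <- length(locus_cols)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (j in seq_len(L)) {
    cell <- as.character(df[[locus_cols[j]]])
    ok <- !is.na(cell) & nzchar(trimws(cell))
    parts <- strsplit(trimws(cell[ok]), sep, fixed = TRUE)
    bad <- lengths(parts) != 2
    if (any(bad))
      stop("locus ", locus_cols[j], ": cannot parse genotype '",
           cell[ok][bad][1], "'")
    a1[ok, j] <- as.integer(vapply(parts, `[`, "", 1))
    a2[ok, j] <- as.integer(vapply(parts, `[`, "", 2))
  }
  genotype_table(a1, a2, as.character(df[[id_col]]), locus_cols,
                 as.character(df[[pop_col]]))
}
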