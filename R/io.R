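#' Read a GENEPOP genotype file
#'
#' Parses the GENEPOP dialect: a title line, one locus name per line (or a
#' single comma-separated line), `POP` separators, and per-individual lines
#' of the form `id , g1 g2 ...` where each genotype concatenates two 2- or
#' 3-digit allele codes.  The digit width is auto-detected per file from the
#' genotype field width; `00`/`000` codes a missing allele and an
#' all-zero genotype a missing genotype.  Each `POP` block becomes one
#' population, labelled `Pop1`, `Pop2`, ... unless the first individual id
#' in the block carries a `label` usable as is (the id of the first
#' individual is the conventional block label and is *not* reused here;
#' sequential labels keep populations unambiguous).
#'
#' @param path path to a GENEPOP text file.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 1]
  if (length(lines) < 3) stop("not a GENEPOP file (too short): ", path)
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("no POP blocks found in ", path)
  locus_lines <- body[seq_len(pop_idx[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("no locus names found in ", path)

  blocks <- split_pop_blocks(body, pop_idx)
  width <- NULL
  ids <- pops <- character(0)
  rows1 <- rows2 <- list()
  for (b in seq_along(blocks)) {
    for (ln in blocks[[b]]) {
      pieces <- strsplit(ln, ",", fixed = TRUE)[[1]]
      if (length(pieces) < 2)
        stop("malformed individual line (no comma): '", ln, "'")
      id <- trimws(pieces[1])
      fields <- strsplit(trimws(paste(pieces[-1], collapse = ",")),
                         "[[:space:]]+")[[1]]
      if (length(fields) != length(loci))
        stop("individual '", id, "': expected ", length(loci),
             " genotypes, found ", length(fields))
      w <- unique(nchar(fields))
      if (length(w) != 1 || !(w %in% c(4L, 6L)))
        stop("malformed allele code width on line: '", ln, "'")
      if (is.null(width)) width <- w / 2
      if (w / 2 != width)
        stop("inconsistent allele code width on line: '", ln, "'")
      a1 <- as.integer(substr(fields, 1, width))
      a2 <- as.integer(substr(fields, width + 1, 2 * width))
      miss <- a1 == 0L | a2 == 0L
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      ids <- c(ids, id); pops <- c(pops, paste0("Pop", b))
      rows1[[length(rows1) + 1]] <- a1
      rows2[[length(rows2) + 1]] <- a2
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate individual ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genotype_table(do.call(rbind, rows1), do.call(rbind, rows2),
                 ids, loci, pops)
}

split_pop_blocks <- function(body, pop_idx) {
  ends <- c(pop_idx[-1] - 1, length(body))
  lapply(seq_along(pop_idx), function(b) {
    rng <- seq(pop_idx[b] + 1, length.out = ends[b] - pop_idx[b])
    body[rng]
  })
}

#' Write a genotype table as a GENEPOP file
#'
#' Emits 3-digit-per-allele coding (so all allele sizes must be below 1000)
#' with `000000` for missing genotypes.  The output is canonical:
#' [read_genepop()] inverts it, and write/read/write round-trips are
#' byte-identical.
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param title title line for the file.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(table, path, title = "badgerabc genotypes") {
  if (length(table$individual_ids) == 0)
    stop("cannot write an empty genotype table")
  mx <- suppressWarnings(max(table$allele2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 1000)
    stop("allele size ", mx, " cannot be encoded with 3 digits")
  enc <- function(a1, a2) {
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    sprintf("%03d%03d", a1, a2)
  }
  out <- c(title, table$locus_names)
  for (pop in populations(table)) {
    out <- c(out, "POP")
    keep <- which(table$population_labels == pop)
    for (i in keep) {
      g <- enc(table$allele1[i, ], table$allele2[i, ])
      out <- c(out, paste0(table$individual_ids[i], " , ",
                           paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read aligned sequences from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return A named character vector of upper-case sequences (alphabet
#'   `A,C,G,T,N,-`), names taken from the headers.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0) stop("no sequences in ", path)
  ids <- names(dna)
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- vapply(as.character(dna),
                 function(s) paste(toupper(s), collapse = ""), "")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) == 0) stop("no sequences to write")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), toupper(seqs))), path)
  invisible(path)
}

#' Read per-individual sample metadata
#'
#' Reads comma- or tab-delimited text (auto-detected from the header line)
#' with columns `id`, `region`, `lat`, `lon` (`latitude`/`longitude` also
#' accepted).  Blank coordinates become `NA`, never zero.  Unknown columns
#' are kept but flagged with a warning.
#'
#' @param path path to the metadata file.
#' @return A data frame with columns `id`, `region`, `lat`, `lon`.
#' @export
read_metadata <- function(path) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  names(df) <- tolower(names(df))
  names(df)[names(df) == "latitude"] <- "lat"
  names(df)[names(df) == "longitude"] <- "lon"
  required <- c("id", "region", "lat", "lon")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning("ignoring unknown metadata columns: ",
            paste(extra, collapse = ", "))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate individual ids in metadata: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  df$lat <- as.numeric(df$lat); df$lon <- as.numeric(df$lon)
  if (any(abs(df$lat) > 90, na.rm = TRUE) ||
      any(abs(df$lon) > 180, na.rm = TRUE))
    stop("coordinates outside [-90,90] / [-180,180]")
  df[required]
}
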