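#' @useDynLib scutpop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov as.dist cmdscale coef cor dist lm median pchisq pf
#'   prcomp pt quantile rnorm runif sd setNames var density approx
#' @importFrom utils read.csv write.csv head combn
NULL

# ---- GenotypeTable -----------------------------------------------------------

#' Construct a microsatellite genotype table
#'
#' The unit of all microsatellite statistics: diploid individuals scored at
#' integer-coded loci (repeat scores), each assigned to exactly one deme
#' (population). Missing genotypes are `NA` in both allele slots.
#'
#' @param ids character vector of individual identifiers (unique).
#' @param demes character vector, deme label per individual.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   codes of each genotype. Codes are positive integers; a genotype is missing
#'   iff both entries are `NA`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, demes, loci, a1, a2) {
  ids <- as.character(ids); demes <- as.character(demes); loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  n <- length(ids)
  if (n < 1L) stop("genotype table needs at least one individual")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  if (length(demes) != n) stop("one deme label per individual required")
  if (length(loci) < 1L) stop("at least one locus required")
  if (!all(dim(a1) == c(n, length(loci))) || !all(dim(a2) == c(n, length(loci))))
    stop("allele matrices must be individuals x loci")
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) stop("both alleles of a genotype must be missing together")
  if (any(a1 < 1L, na.rm = TRUE) || any(a2 < 1L, na.rm = TRUE))
    stop("allele codes must be positive integers")
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, demes = demes, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$ids), "individuals,", length(x$loci),
      "loci,", length(unique(x$demes)), "demes\n")
  invisible(x)
}

#' Deme labels of a genotype table
#' @param gt a `genotype_table`.
#' @return Character vector of distinct deme labels in order of appearance.
#' @export
deme_labels <- function(gt) unique(gt$demes)

#' Read a GenePop genotype file
#'
#' Parses the 2- or 3-digit-allele GenePop dialect. Demes are taken from the
#' `POP` blocks and named after the first individual of each block (the usual
#' GenePop convention); alleles coded `00`/`000` map to missing.
#'
#' @param path file path.
#' @return A [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("GenePop file too short: ", path)
  body <- lines[-1L]                       # drop title line
  is_pop <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("no POP block found in ", path)
  loci <- trimws(unlist(strsplit(body[seq_len(first_pop - 1L)], ",")))
  loci <- loci[nzchar(loci)]
  n_loci <- length(loci)
  ids <- character(); demes <- character()
  a1 <- NULL; a2 <- NULL
  pop_idx <- 0L; cur_deme <- NA_character_
  for (i in seq(first_pop, length(body))) {
    ln <- body[i]
    if (grepl("^\\s*pop\\s*$", ln, ignore.case = TRUE)) {
      pop_idx <- pop_idx + 1L; cur_deme <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed GenePop individual line ", i + 1L, ": ", ln)
    id <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
    if (length(toks) != n_loci)
      stop("line ", i + 1L, ": expected ", n_loci, " genotypes, found ",
           length(toks))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("line ", i + 1L, ": genotypes must be 4 or 6 digits wide")
    d <- w / 2L
    x1 <- as.integer(substr(toks, 1L, d))
    x2 <- as.integer(substr(toks, d + 1L, w))
    x1[x1 == 0L] <- NA_integer_; x2[x2 == 0L] <- NA_integer_
    miss <- is.na(x1) | is.na(x2)
    x1[miss] <- NA_integer_; x2[miss] <- NA_integer_
    if (is.na(cur_deme)) {
      # name the deme after the first individual, minus a numeric suffix
      cur_deme <- sub("_[0-9]+$", "", id)
      if (!nzchar(cur_deme)) cur_deme <- id
    }
    ids <- c(ids, id); demes <- c(demes, cur_deme)
    a1 <- rbind(a1, x1); a2 <- rbind(a2, x2)
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  genotype_table(ids, demes, loci, a1, a2)
}

#' Write a genotype table in GenePop format
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param digits allele field width, 2 or 3.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, digits = 3L) {
  stopifnot(inherits(gt, "genotype_table"), digits %in% c(2L, 3L))
  if (any(gt$a1 >= 10^digits, na.rm = TRUE) || any(gt$a2 >= 10^digits, na.rm = TRUE))
    stop("allele codes exceed the chosen GenePop field width")
  fmt <- function(x) {
    out <- formatC(ifelse(is.na(x), 0L, x), width = digits, flag = "0")
    out
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines("scutpop genotype export", con)
  writeLines(gt$loci, con)
  for (deme in deme_labels(gt)) {
    writeLines("POP", con)
    rows <- which(gt$demes == deme)
    for (r in rows) {
      g <- paste0(fmt(gt$a1[r, ]), fmt(gt$a2[r, ]))
      writeLines(paste0(gt$ids[r], " , ", paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

# ---- SequenceAlignment -------------------------------------------------------

#' Construct a haploid sequence alignment
#'
#' @param ids sequence identifiers.
#' @param demes deme label per sequence.
#' @param seqs character vector of equal-length sequences over `{A,C,G,T,-,N}`.
#' @return An object of class `seq_alignment`.
#' @export
seq_alignment <- function(ids, demes, seqs) {
  ids <- as.character(ids); demes <- as.character(demes)
  seqs <- toupper(as.character(seqs))
  if (length(seqs) < 1L) stop("alignment needs at least one sequence")
  if (length(unique(nchar(seqs))) != 1L)
    stop("all sequences in an alignment must have equal length")
  if (length(ids) != length(seqs) || length(demes) != length(seqs))
    stop("ids, demes and sequences must align")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) stop("sequence contains characters outside {A,C,G,T,-,N}")
  structure(list(ids = ids, demes = demes, seqs = seqs,
                 length = nchar(seqs[1L])), class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("seq_alignment:", length(x$seqs), "sequences of length", x$length, "\n")
  invisible(x)
}

#' Read a FASTA alignment with deme labels in the identifiers
#'
#' Sequences are upper-cased and length-checked. The deme of each sequence is
#' the identifier text before the first `deme_delim` (whole id if absent).
#'
#' @param path FASTA file.
#' @param deme_delim delimiter separating deme label from the rest of the id.
#' @return A [seq_alignment()].
#' @export
read_fasta_alignment <- function(path, deme_delim = "_") {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop("empty FASTA file: ", path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1L), collapse = ""))
  ids <- names(dna)
  demes <- vapply(strsplit(ids, deme_delim, fixed = TRUE), `[`, character(1L), 1L)
  seq_alignment(ids, demes, seqs)
}

#' Write a sequence alignment as FASTA
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(aln$seqs))
    writeLines(c(paste0(">", aln$ids[i]), aln$seqs[i]), con)
  invisible(path)
}

# ---- SiteTable ---------------------------------------------------------------

.site_cols <- c("species", "population", "abbreviation", "latitude",
                "longitude", "altitude", "bio2", "bio8", "bio9", "bio13",
                "bio18", "bio19")

#' Read a site table (coordinates plus bioclimatic variables)
#'
#' Expects a CSV with columns `species, population, abbreviation, latitude,
#' longitude, altitude, bio2, bio8, bio9, bio13, bio18, bio19`. bio2/8/9 are
#' temperatures (deg C); bio13/18/19 precipitation (mm); altitude in metres.
#'
#' @param path CSV path.
#' @return A data frame with one row per population, abbreviations as row
#'   names.
#' @export
read_site_table <- function(path) {
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse site table: ",
                                          conditionMessage(e)))
  names(df) <- tolower(names(df))
  missing_cols <- setdiff(.site_cols, names(df))
  if (length(missing_cols))
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) < 1L) stop("site table has no rows")
  if (anyDuplicated(df$abbreviation)) stop("population labels must be unique")
  if (any(df$latitude < -90 | df$latitude > 90)) stop("latitude out of range")
  if (any(df$longitude < -180 | df$longitude > 180)) stop("longitude out of range")
  rownames(df) <- df$abbreviation
  df[.site_cols]
}

#' The packaged Scutellaria sampling-site table
#'
#' Nine populations (six *S. barbata*, three *S. taipeiensis*) with WGS84
#' coordinates, altitude and the six retained bioclimatic variables.
#'
#' @return Site data frame (see [read_site_table()]).
#' @export
scutellaria_sites <- function() {
  read_site_table(system.file("extdata", "scutellaria_sites.csv",
                              package = "scutpop", mustWork = TRUE))
}

#' Write a site table as CSV
#' @param sites site data frame (see [read_site_table()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  write.csv(sites[.site_cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- DistanceMatrix ----------------------------------------------------------

#' Construct a labelled symmetric distance matrix over populations
#'
#' @param values numeric n x n matrix, symmetric with zero diagonal. Negative
#'   off-diagonal entries are only allowed for `kind = "linearized_fst"`.
#' @param labels population labels in matrix order.
#' @param kind a tag (`"genetic"`, `"geographic"`, `"environmental"`,
#'   `"linearized_fst"`, ...).
#' @return A `dist_matrix` object (matrix with attributes).
#' @export
dist_matrix <- function(values, labels = rownames(values), kind = "generic") {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels) || length(labels) != n) stop("labels must match matrix order")
  if (max(abs(values - t(values))) > 1e-9)
    stop("distance matrix is not symmetric (tolerance 1e-9)")
  if (max(abs(diag(values))) > 1e-12) stop("distance matrix diagonal must be zero")
  if (kind != "linearized_fst" && any(values < -1e-12))
    stop("negative distances only permitted for linearized-F_ST matrices")
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix"), kind = kind)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", attr(x, "kind"), "), ", nrow(x), " populations\n", sep = "")
  print(unclass(x)[,]); invisible(x)
}

#' Unfold the strict upper triangle of a distance matrix
#'
#' Row-major order: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). The inverse
#' is [refold_upper()].
#'
#' @param m a [dist_matrix()] (or symmetric matrix), n >= 2.
#' @return Numeric vector of length n(n-1)/2.
#' @export
unfold_upper <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n < 2L) stop("need at least two populations")
  if (max(abs(m - t(m))) > 1e-9) stop("matrix is not symmetric")
  t(m)[lower.tri(m)]
}

#' Refold an unfolded upper triangle into a symmetric matrix
#' @param v vector from [unfold_upper()].
#' @param labels optional labels.
#' @return Symmetric matrix with zero diagonal.
#' @export
refold_upper <- function(v, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9) stop("vector length is not n(n-1)/2")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v   # column-major lower == row-major upper of t(m)
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}
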