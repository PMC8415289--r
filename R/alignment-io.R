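#' @importFrom stats median p.adjust quantile rbinom rexp rgamma rmultinom
#'   runif sd setNames t.test var vcov coef logLik dist
#' @importFrom utils combn read.delim write.table head
NULL

VALID_BASES <- c("A", "C", "G", "T")
MISSING_BASES <- c("N", "-")
# IUPAC ambiguity codes other than N; mapped to N on read with a warning.
IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Construct a sequence alignment object
#'
#' A `seq_alignment` is a character matrix (rows = individuals, columns =
#' sites, entries in \{A,C,G,T,N,-\}) carrying a locus name. All records
#' must share one length and identifiers must be unique.
#'
#' @param sequences character vector of equal-length sequences
#' @param ids character vector of unique identifiers
#' @param locus_name locus label, e.g. "CytB"
#' @return an object of class `seq_alignment`
#' @export
seq_alignment <- function(sequences, ids = NULL, locus_name = "locus") {
  if (length(sequences) == 0L) stop("empty alignment: no sequences given")
  if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("alignment-length error: sequences differ in length (",
         paste(unique(lens), collapse = ", "), ")")
  }
  if (lens[1] == 0L) stop("alignment-length error: zero-length sequences")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  rownames(mat) <- ids
  mat[mat == "U"] <- "T"
  bad <- !(mat %in% c(VALID_BASES, MISSING_BASES, IUPAC_AMBIG))
  if (any(bad)) {
    stop("invalid-symbol error: characters ",
         paste(unique(mat[bad]), collapse = ", "), " are not IUPAC")
  }
  ambig <- mat %in% IUPAC_AMBIG
  if (any(ambig)) {
    warning(sum(ambig), " IUPAC ambiguity code(s) mapped to N")
    mat[ambig] <- "N"
  }
  structure(list(seq = mat, locus_name = locus_name, L = ncol(mat)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("<seq_alignment> ", nrow(x$seq), " sequences x ", x$L, " bp (",
      x$locus_name, ")\n", sep = "")
  invisible(x)
}

n_seq <- function(aln) nrow(aln$seq)

#' Read a FASTA alignment
#'
#' Wraps `ape::read.FASTA`; sequences are uppercased, order preserved, and
#' validated to a common length. IUPAC ambiguity codes other than N are
#' mapped to N with a warning.
#'
#' @param path FASTA file (wrapped or single-line)
#' @param locus_name optional locus label; defaults to the file stem
#' @return a [seq_alignment()]
#' @export
read_alignment <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (length(dna) == 0L) stop("empty-input error: no FASTA records in ", path)
  seqs <- vapply(as.character(dna),
                 function(s) paste(toupper(s), collapse = ""), character(1))
  if (is.null(locus_name)) locus_name <- sub("\\.[^.]*$", "", basename(path))
  seq_alignment(seqs, ids = names(dna), locus_name = locus_name)
}

#' Write a FASTA alignment
#' @param aln a [seq_alignment()]
#' @param path output path
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_seq(aln))) {
    writeLines(c(paste0(">", rownames(aln$seq)[i]),
                 paste(aln$seq[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a population map
#'
#' Two-column TSV (id, population) with optional `lat` and `lon` columns.
#' @param path TSV path
#' @return a `population_map`: data.frame with columns id, population and
#'   optionally lat, lon
#' @export
read_population_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("population map needs at least id and population columns")
  names(df)[1:2] <- c("id", "population")
  population_map(df$id, df$population,
                 lat = if ("lat" %in% names(df)) df$lat else NULL,
                 lon = if ("lon" %in% names(df)) df$lon else NULL)
}

#' Construct a population map
#' @param ids sample identifiers (unique)
#' @param populations population label per id
#' @param lat,lon optional decimal-degree coordinates per id
#' @export
population_map <- function(ids, populations, lat = NULL, lon = NULL) {
  if (anyDuplicated(ids)) stop("duplicate identifiers in population map")
  if (length(ids) != length(populations)) stop("ids and populations differ in length")
  df <- data.frame(id = as.character(ids),
                   population = as.character(populations),
                   stringsAsFactors = FALSE)
  if (!is.null(lat)) df$lat <- lat
  if (!is.null(lon)) df$lon <- lon
  class(df) <- c("population_map", "data.frame")
  df
}

# population factor aligned to alignment rows; errors if any id unmapped
pop_factor <- function(aln, pm) {
  idx <- match(rownames(aln$seq), pm$id)
  if (anyNA(idx)) {
    stop("mapping error: identifiers not in population map: ",
         paste(rownames(aln$seq)[is.na(idx)], collapse = ", "))
  }
  factor(pm$population[idx])
}

# TRUE where the base is informative (not N or gap)
informative <- function(m) m %in% VALID_BASES

#' Collapse an alignment into a haplotype spectrum
#'
#' Two sequences share a haplotype iff they agree at every site where both
#' carry a non-missing base (N and - are missing). A sequence compatible
#' with more than one established haplotype joins the first-encountered one
#' in input order.
#'
#' @param aln a [seq_alignment()]
#' @param pm a [population_map()] covering every alignment id
#' @return a `haplotype_spectrum`: list with `haplotypes` (representative
#'   sequences), `counts` (population x haplotype integer matrix), `n`, `k`,
#'   and `assignment` (haplotype index per individual)
#' @export
collapse_haplotypes <- function(aln, pm) {
  if (n_seq(aln) == 0L) stop("empty alignment")
  pops <- pop_factor(aln, pm)
  m <- aln$seq
  ok <- matrix(m %in% VALID_BASES, nrow = nrow(m))
  reps <- integer(0)            # row index of each haplotype representative
  assign_idx <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    hit <- 0L
    for (h in seq_along(reps)) {
      r <- reps[h]
      both <- ok[i, ] & ok[r, ]
      if (!any(m[i, both] != m[r, both])) { hit <- h; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    assign_idx[i] <- hit
  }
  k <- length(reps)
  counts <- matrix(0L, nrow = nlevels(pops), ncol = k,
                   dimnames = list(levels(pops), paste0("H", seq_len(k))))
  for (i in seq_len(nrow(m))) {
    counts[as.integer(pops[i]), assign_idx[i]] <-
      counts[as.integer(pops[i]), assign_idx[i]] + 1L
  }
  structure(list(haplotypes = apply(m[reps, , drop = FALSE], 1, paste,
                                    collapse = ""),
                 counts = counts, n = nrow(m), k = k,
                 assignment = assign_idx),
            class = "haplotype_spectrum")
}

#' Pairwise nucleotide differences (pairwise deletion)
#'
#' Raw mismatch counts over sites where both sequences carry a non-missing
#' base; no substitution-model correction.
#'
#' @param aln a [seq_alignment()]
#' @return a `diff_matrix`: list of `d` (difference counts) and
#'   `sites_compared`, both symmetric n x n
#' @export
pairwise_differences <- function(aln) {
  n <- n_seq(aln)
  if (n < 2) stop("need at least two sequences")
  m <- aln$seq
  ok <- matrix(m %in% VALID_BASES, nrow = n)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  sc <- matrix(0L, n, n, dimnames = dimnames(d))
  diag(sc) <- as.integer(rowSums(ok))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- ok[i, ] & ok[j, ]
      nd <- sum(m[i, both] != m[j, both])
      d[i, j] <- d[j, i] <- nd
      sc[i, j] <- sc[j, i] <- sum(both)
    }
  }
  structure(list(d = d, sites_compared = sc, L = aln$L), class = "diff_matrix")
}

#' Private haplotypes of a focal population
#'
#' @param spec a [collapse_haplotypes()] spectrum
#' @param focal focal population label
#' @return list with `count` (haplotypes seen only in the focal population)
#'   and `percent` (100 * count / haplotypes observed in focal)
#' @export
private_haplotype_fraction <- function(spec, focal) {
  if (!focal %in% rownames(spec$counts)) {
    stop("unknown-population error: ", focal)
  }
  foc <- spec$counts[focal, ]
  oth <- colSums(spec$counts[setdiff(rownames(spec$counts), focal), ,
                             drop = FALSE])
  observed <- sum(foc > 0)
  if (observed == 0L) stop("focal population has no samples")
  count <- sum(foc > 0 & oth == 0)
  list(count = count, percent = 100 * count / observed)
}
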