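#' @useDynLib islandclock, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# IUPAC DNA alphabet accepted in alignments; '?' is tolerated on input and
# mapped to N.
IUPAC_SYMBOLS <- c("A", "C", "G", "T", "U", "-", "N",
                   "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

# symbols carrying full state information for pairwise distance purposes
UNAMBIGUOUS_BASES <- c("A", "C", "G", "T")

#' Construct a DNA alignment
#'
#' A `dna_alignment` is a character matrix of upper-case IUPAC symbols with
#' unique taxon ids as row names. Gaps (`-`) and ambiguity codes are legal
#' residues and are never stripped.
#'
#' @param x character matrix (taxa in rows) or list/vector of equal-length
#'   sequence strings named by taxon.
#' @param partition_bounds optional integer matrix or list of `c(start, end)`
#'   1-based closed column intervals, one per locus.
#' @return object of class `dna_alignment`.
#' @export
dna_alignment <- function(x, partition_bounds = NULL) {
  if (!is.matrix(x)) {
    if (is.null(names(x))) stop("sequences must be named by taxon", call. = FALSE)
    lens <- vapply(x, nchar, integer(1))
    if (length(unique(lens)) > 1L)
      stop("alignment is ragged: sequence lengths differ", call. = FALSE)
    nm <- names(x)
    x <- do.call(rbind, lapply(x, function(s) strsplit(s, "")[[1]]))
    rownames(x) <- nm
  }
  x[] <- toupper(x)
  x[x == "?"] <- "N"
  if (is.null(rownames(x)) || anyNA(rownames(x)) || any(rownames(x) == ""))
    stop("all taxa must be named", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate taxon ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]),
                                        collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.vector(x)), IUPAC_SYMBOLS)
  if (length(bad))
    stop("non-IUPAC symbols in alignment: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (nrow(x) < 1L) stop("alignment needs at least one sequence", call. = FALSE)
  structure(x, class = c("dna_alignment", "matrix"),
            partition_bounds = partition_bounds)
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d taxa, %d sites\n", nrow(x), ncol(x)))
  invisible(x)
}

n_taxa <- function(aln) nrow(aln)
n_sites <- function(aln) ncol(aln)

#' Read a multiple sequence alignment
#'
#' Supports FASTA and relaxed sequential PHYLIP (whitespace-delimited names).
#' Gaps, missing data and ambiguity codes are retained.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty alignment file: ", path, call. = FALSE)
  if (format == "fasta") {
    if (!grepl("^>", lines[1]))
      stop("not FASTA: first line lacks '>'", call. = FALSE)
    x <- ape::read.FASTA(path)
    if (!length(x) || any(lengths(x) == 0L))
      stop("FASTA record with empty sequence", call. = FALSE)
    seqs <- vapply(as.character(x), paste, character(1), collapse = "")
    names(seqs) <- sub("\\s.*$", "", names(x))
  } else {
    hd <- scan(text = lines[1], what = character(), quiet = TRUE)
    if (length(hd) != 2L || anyNA(suppressWarnings(as.integer(hd))))
      stop("not relaxed PHYLIP: header must be '<ntaxa> <nsites>'", call. = FALSE)
    nt <- as.integer(hd[1])
    body <- lines[-1]
    if (length(body) != nt)
      stop("PHYLIP: expected ", nt, " sequence lines, found ", length(body),
           call. = FALSE)
    parts <- lapply(body, function(l) scan(text = l, what = character(), quiet = TRUE))
    ids <- vapply(parts, `[`, character(1), 1L)
    seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
    names(seqs) <- ids
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L)
    stop("alignment is ragged: sequence lengths differ", call. = FALSE)
  dna_alignment(seqs)
}

#' Write an alignment
#'
#' @param aln a [dna_alignment()].
#' @param path output file.
#' @param format `"fasta"` or `"phylip-relaxed"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip-relaxed")) {
  format <- match.arg(format)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  if (format == "fasta") {
    out <- as.vector(rbind(paste0(">", rownames(aln)), seqs))
  } else {
    out <- c(paste(nrow(aln), ncol(aln)),
             paste(rownames(aln), seqs))
  }
  writeLines(out, path)
  invisible(path)
}

#' Pairwise uncorrected p-distances
#'
#' Proportion of differing sites among columns where both sequences carry an
#' unambiguous base (A, C, G or T). Columns with a gap or any ambiguity code
#' in either sequence are excluded from the denominator. A pair with no
#' comparable column gets `NA`.
#'
#' @param aln a [dna_alignment()].
#' @return symmetric numeric matrix of distances.
#' @export
p_distance_matrix <- function(aln) {
  m <- unclass(aln)
  nt <- nrow(m)
  ok <- matrix(m %in% UNAMBIGUOUS_BASES, nrow = nt)
  d <- matrix(0, nt, nt, dimnames = list(rownames(m), rownames(m)))
  if (nt < 2L) return(d)
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      comp <- ok[i, ] & ok[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <- if (nc == 0L) NA_real_ else
        sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Drop near-identical sequences
#'
#' Greedy de-duplication in input order: a sequence is discarded when its
#' uncorrected p-distance to an already retained sequence is below
#' `threshold`. Pairs with no jointly unambiguous column are treated as
#' distinct (both kept).
#'
#' @param aln a [dna_alignment()].
#' @param threshold proportion in `[0, 1)`; the default drops one of any
#'   pair closer than 0.003.
#' @return the filtered [dna_alignment()]; deterministic, keeps the first
#'   member of each cluster.
#' @export
dedupe_alignment <- function(aln, threshold = 0.003) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  nt <- nrow(aln)
  if (nt == 1L) return(aln)
  d <- p_distance_matrix(aln)
  keep <- 1L
  for (i in seq_len(nt)[-1]) {
    di <- d[i, keep]
    if (!any(!is.na(di) & di < threshold)) keep <- c(keep, i)
  }
  dna_alignment(unclass(aln)[keep, , drop = FALSE],
                partition_bounds = attr(aln, "partition_bounds"))
}
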