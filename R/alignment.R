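#' Construct a multiple sequence alignment object
#'
#' The basic container of the package: an equal-length set of DNA sequences
#' with unique sample ids. Sequences are uppercased and any character outside
#' the alphabet \code{A, C, G, T, N, -} is replaced by \code{N} with a
#' warning. Site coordinates are 1-based and inclusive everywhere.
#'
#' @param sequences character vector of sequences; names are used as sample
#'   ids when `ids` is not given.
#' @param ids sample identifiers, one per sequence; must be unique.
#' @return An object of class `coi_alignment` with elements `ids`, `seq`
#'   (character vector of sequences) and `length` (alignment width in bp).
#' @examples
#' aln <- coi_alignment(c(s1 = "ACGTACGTAC", s2 = "ACGTACGTAT"))
#' aln$length
#' @export
coi_alignment <- function(sequences, ids = names(sequences)) {
  if (length(sequences) == 0L) stop("alignment must contain at least one sequence")
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs))) stop("empty sequence for record ", ids[!nzchar(seqs)][1])
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    stop("alignment error: record '", ids[bad], "' has length ", lens[bad],
         " but '", ids[1], "' has length ", lens[1])
  }
  dirty <- grepl("[^ACGTN-]", seqs)
  if (any(dirty)) {
    warning("characters outside {A,C,G,T,N,-} mapped to N in ",
            sum(dirty), " record(s)")
    seqs[dirty] <- gsub("[^ACGTN-]", "N", seqs[dirty])
  }
  structure(list(ids = ids, seq = unname(seqs), length = lens[1]),
            class = "coi_alignment")
}

#' Read a multiple sequence alignment from a FASTA file
#'
#' Accepts wrapped or unwrapped multi-record FASTA. All records must have
#' identical length (the input must already be aligned); no alignment is
#' performed here.
#'
#' @param path path to a FASTA file.
#' @return A [coi_alignment()] object.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  coi_alignment(as.character(set), ids = ids)
}

#' Write an alignment to FASTA
#'
#' @param aln a [coi_alignment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "coi_alignment"))
  set <- Biostrings::BStringSet(setNames(aln$seq, aln$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Two-column TSV (sample id, population label), no header. When an
#' alignment is supplied every alignment sample must be covered.
#'
#' @param path path to the TSV file.
#' @param aln optional [coi_alignment()] used to validate coverage.
#' @return Named character vector mapping sample id to population label.
#' @export
read_population_map <- function(path, aln = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("sample_id", "population"))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in population map")
  pops <- setNames(df$population, df$sample_id)
  if (!is.null(aln)) validate_population_map(pops, aln)
  pops
}

validate_population_map <- function(pops, aln) {
  missing <- setdiff(aln$ids, names(pops))
  if (length(missing))
    stop("population map misses sample(s): ", paste(missing, collapse = ", "))
  pops[aln$ids]
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat("<coi_alignment> ", length(x$ids), " sequences x ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a [coi_alignment()].
#' @return integer.
#' @export
n_sequences <- function(aln) length(aln$ids)

# Character matrix view (sequences in rows, sites in columns).
aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$seq), ncol = aln$length, byrow = TRUE)
  rownames(m) <- aln$ids
  m
}

#' Pairwise difference and comparable-site matrices
#'
#' For every unordered pair of sequences, counts sites at which both carry an
#' unambiguous base (`A/C/G/T`) and, of those, sites at which they differ.
#' Sites where either member of a pair carries `N` or `-` are excluded from
#' that pair's comparison (pairwise deletion).
#'
#' @param aln a [coi_alignment()].
#' @return List with symmetric integer matrices `diffs` and `comparable`.
#' @export
pairwise_differences <- function(aln) {
  M <- aln_matrix(aln)
  n <- nrow(M)
  V <- matrix(as.numeric(M %in% DNA_STATES), nrow = n)
  comparable <- tcrossprod(V)
  matches <- matrix(0, n, n)
  for (b in DNA_STATES) {
    B <- matrix(as.numeric(M == b), nrow = n)
    matches <- matches + tcrossprod(B)
  }
  diffs <- comparable - matches
  dimnames(diffs) <- dimnames(comparable) <- list(aln$ids, aln$ids)
  list(diffs = round(diffs), comparable = round(comparable))
}

# Subset an alignment by sample ids or indices.
subset_alignment <- function(aln, which) {
  if (is.character(which)) which <- match(which, aln$ids)
  structure(list(ids = aln$ids[which], seq = aln$seq[which], length = aln$length),
            class = "coi_alignment")
}
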