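#' Collapse aligned sequences into haplotypes
#'
#' Exact string identity defines a haplotype: `N` and `-` are ordinary
#' characters for identity purposes (no wildcard matching, no similarity
#' threshold). Haplotype ids are assigned in descending count order with
#' ties broken by first occurrence in the alignment, so the naming is fully
#' deterministic.
#'
#' @param aln a [coi_alignment()].
#' @param pops optional named character vector (sample id -> population
#'   label); when given, per-population counts are tallied.
#' @param name_map optional named character vector renaming the default
#'   `H001`-style ids (e.g. `c(H001 = "ECH01")`).
#' @return An object of class `haplotype_table`: a list with vectors
#'   `hap_id`, `sequence`, `count`, list `members` (sample ids per
#'   haplotype), matrix `pop_counts` (haplotype x population; `NULL` when no
#'   map is supplied), and scalars `n_sequences`, `seq_length`.
#' @examples
#' aln <- coi_alignment(c(a = "ACGT", b = "ACGT", c = "ACTT"))
#' ht <- collapse_haplotypes(aln)
#' ht$count
#' @export
collapse_haplotypes <- function(aln, pops = NULL, name_map = NULL) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (!is.null(pops)) pops <- validate_population_map(pops, aln)
  first_seen <- !duplicated(aln$seq)
  uniq <- aln$seq[first_seen]
  idx <- match(aln$seq, uniq)               # haplotype index per sequence
  counts <- tabulate(idx, nbins = length(uniq))
  ord <- order(-counts, seq_along(uniq))    # desc count, ties by first occurrence
  rank_of <- match(seq_along(uniq), ord)
  hap_id <- sprintf("H%03d", seq_along(uniq))
  members <- split(aln$ids, rank_of[idx])
  members <- members[as.character(seq_along(uniq))]
  names(members) <- hap_id
  pop_counts <- NULL
  if (!is.null(pops)) {
    pop_levels <- unique(unname(pops))
    pop_counts <- vapply(members, function(m)
      tabulate(factor(pops[m], levels = pop_levels), nbins = length(pop_levels)),
      integer(length(pop_levels)))
    # vapply drops to a vector when there is a single population
    pop_counts <- t(matrix(pop_counts, nrow = length(pop_levels)))
    colnames(pop_counts) <- pop_levels
    rownames(pop_counts) <- hap_id
  }
  if (!is.null(name_map)) {
    hit <- hap_id %in% names(name_map)
    hap_id[hit] <- unname(name_map[hap_id[hit]])
    names(members) <- hap_id
    if (!is.null(pop_counts)) rownames(pop_counts) <- hap_id
  }
  structure(list(hap_id = hap_id,
                 sequence = uniq[ord],
                 count = counts[ord],
                 members = members,
                 pop_counts = pop_counts,
                 n_sequences = length(aln$ids),
                 seq_length = aln$length),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", length(x$hap_id), " haplotypes from ",
      x$n_sequences, " sequences (", x$seq_length, " bp)\n", sep = "")
  invisible(x)
}

#' Number of haplotypes in a table
#' @param ht a `haplotype_table`.
#' @return integer.
#' @export
n_haplotypes <- function(ht) length(ht$hap_id)

#' One-record-per-haplotype alignment
#'
#' @param ht a `haplotype_table`.
#' @return A [coi_alignment()] whose records are the distinct haplotype
#'   sequences, named by haplotype id.
#' @export
hap_alignment <- function(ht) {
  coi_alignment(setNames(ht$sequence, ht$hap_id))
}

#' @method as.data.frame haplotype_table
#' @export
as.data.frame.haplotype_table <- function(x, ...) {
  pops <- if (is.null(x$pop_counts)) "" else
    apply(x$pop_counts, 1, function(r) {
      r <- r[r > 0]
      paste(sprintf("%s:%d", names(r), r), collapse = ";")
    })
  data.frame(hap_id = x$hap_id, count = x$count, populations = pops,
             sequence = x$sequence, stringsAsFactors = FALSE)
}

#' Write a haplotype table as TSV
#'
#' Columns: hap_id, count, populations (`POP:count` pairs separated by
#' semicolons), sequence.
#'
#' @param ht a `haplotype_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  utils::write.table(as.data.frame(ht), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
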