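# Aligned-sequence container: a character matrix (rows = sequences, columns =
# alignment positions), with attributes recording the sequence type and the
# original 1-based coordinates of the surviving columns.

missing_chars <- function(type) {
  if (type == "protein") c("-", ".", "X", "?", "*") else c("-", ".", "N", "?")
}

#' Construct an alignment from sequence strings
#'
#' @param x named character vector of equal-length aligned sequences, or a
#'   character matrix (rows = sequences)
#' @param type `"codon"` (in-frame nucleotide) or `"protein"`
#' @return a `cyp_alignment` object
#' @export
new_alignment <- function(x, type = c("codon", "protein")) {
  type <- match.arg(type)
  if (is.matrix(x)) {
    m <- x
  } else {
    if (length(unique(nchar(x))) > 1L)
      stop("ragged alignment: sequences differ in length", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  if (type == "codon" && ncol(m) %% 3L != 0L)
    stop("frame error: codon alignment length ", ncol(m),
         " is not divisible by 3", call. = FALSE)
  structure(m, class = c("cyp_alignment", class(m)),
            type = type, column_map = seq_len(n_units(m, type)))
}

n_units <- function(m, type) if (type == "codon") ncol(m) %/% 3L else ncol(m)

aln_type <- function(aln) attr(aln, "type")

#' @export
print.cyp_alignment <- function(x, ...) {
  cat("<cyp_alignment> ", nrow(x), " sequences x ", ncol(x), " columns (",
      aln_type(x), ")\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Sequences must all have the same length; for codon alignments the length
#' must additionally be divisible by 3. Gaps are `'-'`; ambiguity codes
#' (`N` for nucleotides, `X` for proteins) are treated as missing data in
#' every downstream computation.
#'
#' @param path FASTA file
#' @param type `"codon"` or `"protein"`
#' @return a `cyp_alignment`
#' @export
read_alignment <- function(path, type = c("codon", "protein")) {
  type <- match.arg(type)
  ss <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(ss))) > 1L)
    stop("ragged alignment in ", path, ": sequence lengths differ",
         call. = FALSE)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  new_alignment(x, type)
}

#' Write an alignment to FASTA
#' @param aln a `cyp_alignment`
#' @param path output file
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Site-filtering policy
#'
#' Columns at which more than `max_gap_fraction` of the sequences show gaps
#' are excluded before distance computation, and missing data within the
#' retained columns are handled per pair (`"pairwise"`) or by dropping every
#' column with any missing value (`"complete"`).
#'
#' @param max_gap_fraction proportion in `[0, 1]`; default 0.20, applied with
#'   strict inequality (a column with exactly 20% gaps is kept)
#' @param deletion `"pairwise"` or `"complete"`
#' @return a `site_filter_policy` list
#' @export
site_filter_policy <- function(max_gap_fraction = 0.20,
                               deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(is.numeric(max_gap_fraction), max_gap_fraction >= 0,
            max_gap_fraction <= 1)
  structure(list(max_gap_fraction = max_gap_fraction, deletion = deletion),
            class = "site_filter_policy")
}

unit_missing_matrix <- function(aln) {
  type <- aln_type(aln)
  miss <- matrix(unclass(aln) %in% missing_chars(type), nrow(aln), ncol(aln))
  if (type == "codon") {
    nu <- ncol(aln) %/% 3L
    # a codon is missing when any of its three nucleotides is missing
    out <- matrix(FALSE, nrow(aln), nu)
    for (k in 1:3) out <- out | miss[, seq(k, ncol(aln), by = 3L), drop = FALSE]
    out
  } else {
    miss
  }
}

#' Remove gap-rich alignment columns
#'
#' Drops every column (codon column for codon alignments) at which the
#' fraction of sequences with missing data is strictly greater than the
#' policy's `max_gap_fraction`. The returned alignment carries a
#' `column_map` attribute giving the original 1-based unit coordinates of
#' the kept columns.
#'
#' @param aln a `cyp_alignment`
#' @param policy a [site_filter_policy()]
#' @return filtered `cyp_alignment`
#' @export
filter_columns <- function(aln, policy = site_filter_policy()) {
  if (nrow(aln) == 0L || ncol(aln) == 0L)
    stop("cannot filter an empty alignment", call. = FALSE)
  miss <- unit_missing_matrix(aln)
  frac <- colMeans(miss)
  keep <- frac <= policy$max_gap_fraction   # strictly-greater rule
  old_map <- attr(aln, "column_map")
  type <- aln_type(aln)
  cols <- if (type == "codon") {
    as.vector(vapply(which(keep), function(u) (3L * (u - 1L) + 1L):(3L * u),
                     integer(3)))
  } else {
    which(keep)
  }
  out <- unclass(aln)[, cols, drop = FALSE]
  structure(out, class = c("cyp_alignment", class(out)),
            type = type, column_map = old_map[keep])
}

comparable_mask <- function(a, b, type) {
  mc <- missing_chars(type)
  !(a %in% mc) & !(b %in% mc)
}

#' Proportion of differing nucleotide sites between two sequences
#'
#' @param a,b equal-length character vectors (or strings) of aligned
#'   nucleotides
#' @param policy a [site_filter_policy()]; under `"pairwise"` deletion only
#'   positions where both sequences are non-missing are compared, under
#'   `"complete"` only positions where neither shows missing data (identical
#'   for a single pair)
#' @return p-distance, or `NA` with a warning when no sites are comparable
#' @export
p_distance <- function(a, b, policy = site_filter_policy()) {
  ab <- as_char_pair(a, b)
  keep <- comparable_mask(ab$a, ab$b, "codon")
  n <- sum(keep)
  if (n == 0L) {
    warning("no comparable sites: p-distance undefined")
    return(NA_real_)
  }
  sum(ab$a[keep] != ab$b[keep]) / n
}

#' Fraction of identical residues between two aligned sequences
#' @inheritParams p_distance
#' @param type `"protein"` or `"codon"`
#' @return identity in `[0, 1]`, `NA` when no sites are comparable
#' @export
identity_fraction <- function(a, b, policy = site_filter_policy(),
                              type = "protein") {
  ab <- as_char_pair(a, b)
  keep <- comparable_mask(ab$a, ab$b, type)
  n <- sum(keep)
  if (n == 0L) {
    warning("no comparable sites: identity undefined")
    return(NA_real_)
  }
  sum(ab$a[keep] == ab$b[keep]) / n
}

as_char_pair <- function(a, b) {
  if (length(a) == 1L && nchar(a[1]) > 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L && nchar(b[1]) > 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b))
    stop("sequences differ in length", call. = FALSE)
  list(a = toupper(a), b = toupper(b))
}

# Convert one row of a codon alignment to integer codons (NA where any
# position is missing/ambiguous). Uses base-4 arithmetic in T,C,A,G order,
# consistent with codon_table_order().
row_to_codons <- function(chars) {
  n <- length(chars) %/% 3L
  b <- match(chars, c("T", "C", "A", "G")) - 1L
  c1 <- b[seq(1L, by = 3L, length.out = n)]
  c2 <- b[seq(2L, by = 3L, length.out = n)]
  c3 <- b[seq(3L, by = 3L, length.out = n)]
  16L * c1 + 4L * c2 + c3 + 1L
}
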