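# Pairwise distance matrices under the gap policies used throughout:
# nucleotide p-distance (optionally Jukes-Cantor corrected), protein JTT
# ML distance, and NG86 synonymous / nonsynonymous distances.

#' Pairwise JTT protein distance
#'
#' Maximum-likelihood distance between two aligned protein sequences under
#' the Jones-Taylor-Thornton replacement matrix (one-parameter optimisation,
#' as implemented in \pkg{phangorn}'s `dist.ml`). Distances above the
#' saturation bound (10 substitutions/site) are clamped and flagged via the
#' `"saturated"` attribute.
#'
#' @param a,b aligned protein sequences (strings or character vectors)
#' @param policy a [site_filter_policy()]
#' @return distance in substitutions/site
#' @export
jtt_distance <- function(a, b, policy = site_filter_policy()) {
  ab <- as_char_pair(a, b)
  keep <- comparable_mask(ab$a, ab$b, "protein")
  if (!any(keep)) stop("no comparable sites for JTT distance", call. = FALSE)
  m <- rbind(s1 = ab$a[keep], s2 = ab$b[keep])
  if (all(m[1, ] == m[2, ])) return(structure(0, saturated = FALSE))
  pd <- phangorn::phyDat(m, type = "AA")
  d <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))[1, 2]
  sat <- d >= 10
  structure(min(d, 10), saturated = sat)
}

#' Pairwise distance matrix for an alignment
#'
#' Applies the gap-rich-column exclusion of `policy` ([filter_columns()]),
#' then computes all pairwise distances. Under `"complete"` deletion every
#' column with any missing value is removed first; under `"pairwise"`
#' deletion each pair is compared on the positions where both members are
#' non-missing.
#'
#' @param aln a `cyp_alignment`
#' @param method `"p"` (nucleotide p-distance), `"jtt"` (protein ML
#'   distance), `"dn"` or `"ds"` (NG86)
#' @param policy a [site_filter_policy()]
#' @param correction correction applied to proportions: `"none"` (default
#'   for `"p"`) or `"jukes_cantor"` (always used for `"dn"`/`"ds"` unless
#'   overridden)
#' @return a `cyp_dist` object: symmetric numeric matrix with attributes
#'   `method`, `policy`, `correction` and `comparable_sites`
#' @export
distance_matrix <- function(aln, method = c("p", "jtt", "dn", "ds"),
                            policy = site_filter_policy(),
                            correction = NULL) {
  method <- match.arg(method)
  if (is.null(correction))
    correction <- if (method %in% c("dn", "ds")) "jukes_cantor" else "none"
  aln <- filter_columns(aln, policy)
  if (policy$deletion == "complete") {
    miss <- unit_missing_matrix(aln)
    keep <- colSums(miss) == 0L
    cm <- attr(aln, "column_map")
    type <- aln_type(aln)
    cols <- if (type == "codon") {
      as.vector(vapply(which(keep), function(u) (3L * (u - 1L) + 1L):(3L * u),
                       integer(3)))
    } else which(keep)
    aln <- structure(unclass(aln)[, cols, drop = FALSE],
                     class = c("cyp_alignment", "matrix", "array"),
                     type = type, column_map = cm[keep])
  }
  n <- nrow(aln)
  labels <- rownames(aln)
  codon_rows <- if (method %in% c("dn", "ds")) {
    lapply(seq_len(n), function(i) row_to_codons(unclass(aln)[i, ]))
  }
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  sites <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      a <- unclass(aln)[i, ]
      b <- unclass(aln)[j, ]
      val <- switch(method,
        p = {
          p <- p_distance(a, b, policy)
          sites[i, j] <- sites[j, i] <-
            sum(comparable_mask(a, b, "codon"))
          if (correction == "jukes_cantor") jukes_cantor(p) else p
        },
        jtt = {
          sites[i, j] <- sites[j, i] <- sum(comparable_mask(a, b, "protein"))
          as.numeric(jtt_distance(a, b, policy))
        },
        dn = ,
        ds = {
          res <- ng86_pair_int(codon_rows[[i]], codon_rows[[j]], correction)
          sites[i, j] <- sites[j, i] <- res$codons
          if (method == "dn") res$dN else res$dS
        })
      D[i, j] <- D[j, i] <- val
    }
  }
  structure(D, class = c("cyp_dist", "matrix", "array"),
            method = method, policy = policy, correction = correction,
            comparable_sites = sites)
}

# dS and dN matrices in one pass (shared codon conversion); used by
# estimate_f where both are always needed
ng86_matrices <- function(aln, policy = site_filter_policy(),
                          correction = "jukes_cantor") {
  aln <- filter_columns(aln, policy)
  n <- nrow(aln)
  labels <- rownames(aln)
  codon_rows <- lapply(seq_len(n), function(i) row_to_codons(unclass(aln)[i, ]))
  DN <- DS <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    res <- ng86_pair_int(codon_rows[[i]], codon_rows[[j]], correction)
    DN[i, j] <- DN[j, i] <- res$dN
    DS[i, j] <- DS[j, i] <- res$dS
  }
  mk <- function(m, method) structure(
    m, class = c("cyp_dist", "matrix", "array"), method = method,
    policy = policy, correction = correction, comparable_sites = NULL)
  list(dN = mk(DN, "dn"), dS = mk(DS, "ds"))
}

#' @export
print.cyp_dist <- function(x, ...) {
  cat("<cyp_dist> method=", attr(x, "method"),
      " deletion=", attr(x, "policy")$deletion,
      " correction=", attr(x, "correction"), "\n", sep = "")
  print(round(unclass(x)[, , drop = FALSE], 4))
  invisible(x)
}

#' Write a distance matrix as TSV with a metadata header
#'
#' Metadata (method, deletion policy, gap threshold, correction) is stored
#' in leading `#` comment lines, followed by a square labelled matrix.
#'
#' @param D a `cyp_dist`
#' @param path output file
#' @export
write_distance_matrix <- function(D, path) {
  pol <- attr(D, "policy")
  hdr <- c(
    paste0("# method=", attr(D, "method")),
    paste0("# deletion=", pol$deletion),
    paste0("# max_gap_fraction=", pol$max_gap_fraction),
    paste0("# correction=", attr(D, "correction"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- cbind(label = rownames(D), as.data.frame(unclass(D)))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#' @param path TSV file
#' @return a `cyp_dist`
#' @export
read_distance_matrix <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$label
  pol <- site_filter_policy(as.numeric(meta$max_gap_fraction %||% 0.2),
                            meta$deletion %||% "pairwise")
  structure(m, class = c("cyp_dist", "matrix", "array"),
            method = meta$method %||% "p", policy = pol,
            correction = meta$correction %||% "none",
            comparable_sites = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
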