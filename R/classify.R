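# Reference-anchored assignment of genes to B/D type and family, and
# discovery of conserved and group-diagnostic alignment sites.

#' Assign query leaves to B/D type by phylogenetic clustering
#'
#' Each query leaf takes the label of the smallest clade containing it whose
#' reference leaves are unanimous in type and whose defining branch support
#' is at least `min_support`; leaves for which no such clade exists are
#' `"unassigned"`. Internal nodes with support below `min_support` are
#' treated as unresolved and skipped.
#'
#' @param tree rooted ape `phylo` with support values as `node.label` (or in
#'   `attr(tree, "support")`)
#' @param reference named character vector mapping reference tip labels to
#'   `"B"` or `"D"`; at least one reference of each type is required
#' @param min_support minimum percent support for a clade to be used
#'   (default 80)
#' @return tibble with columns `leaf`, `type`, `clade_size`, `support`
#' @export
assign_type <- function(tree, reference, min_support = 80) {
  if (!ape::is.rooted(tree)) stop("assign_type requires a rooted tree",
                                  call. = FALSE)
  if (length(unique(reference)) < 2L ||
      !all(c("B", "D") %in% unique(reference)))
    stop("need at least one labeled reference of each type (B and D)",
         call. = FALSE)
  if (!all(names(reference) %in% tree$tip.label))
    stop("reference label(s) not in tree", call. = FALSE)
  tips <- tree$tip.label
  n <- length(tips)
  support <- node_support(tree)
  clades <- node_tip_descendants(tree)
  queries <- setdiff(tips, names(reference))
  res <- lapply(queries, function(q) {
    node <- match(q, tips)
    repeat {
      parent_edge <- which(tree$edge[, 2] == node)
      if (length(parent_edge) == 0L) break  # reached the root
      node <- tree$edge[parent_edge, 1]
      clade_tips <- tips[clades[[node]]]
      refs <- reference[intersect(names(reference), clade_tips)]
      sup <- support[node - n]
      if (length(refs) == 0L) next
      if (!is.na(sup) && sup < min_support) next
      if (length(unique(refs)) == 1L) {
        return(tibble::tibble(leaf = q, type = unname(refs[1]),
                              clade_size = length(clade_tips),
                              support = sup))
      }
      # mixed references: no smaller unanimous clade can exist above here
      break
    }
    tibble::tibble(leaf = q, type = "unassigned",
                   clade_size = NA_integer_, support = NA_real_)
  })
  dplyr::bind_rows(res)
}

node_support <- function(tree) {
  n <- ape::Ntip(tree)
  sup <- attr(tree, "support")
  if (is.null(sup) && !is.null(tree$node.label))
    sup <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(sup)) sup <- rep(NA_real_, tree$Nnode)
  sup
}

node_tip_descendants <- function(tree) {
  n <- ape::Ntip(tree)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Group sequences into families and subfamilies by protein identity
#'
#' Single-linkage clustering of pairwise identity: sequences chained by
#' identities of at least `family_threshold` share a family, and within it
#' chains at `subfamily_threshold` share a subfamily (nesting holds by
#' construction of single linkage). Pairs with undefined identity (no
#' comparable sites) are treated as identity 0 with a warning.
#'
#' @param aln a protein `cyp_alignment`
#' @param family_threshold minimum identity for family membership (0.40)
#' @param subfamily_threshold minimum identity for subfamily membership
#'   (0.55)
#' @param policy a [site_filter_policy()]
#' @return tibble with columns `sequence`, `family`, `subfamily` (integer
#'   cluster ids; subfamily ids are nested labels `family.k`)
#' @export
assign_family_by_identity <- function(aln, family_threshold = 0.40,
                                      subfamily_threshold = 0.55,
                                      policy = site_filter_policy()) {
  n <- nrow(aln)
  labels <- rownames(aln)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    id <- withCallingHandlers(
      identity_fraction(unclass(aln)[i, ], unclass(aln)[j, ], policy,
                        type = aln_type(aln)),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.na(id)) {
      warning("undefined identity for pair (", labels[i], ", ", labels[j],
              "): treated as 0")
      id <- 0
    }
    D[i, j] <- D[j, i] <- 1 - id
  }
  fam <- single_linkage_groups(D, 1 - family_threshold)
  subfam_raw <- single_linkage_groups(D, 1 - subfamily_threshold)
  sub_label <- paste(fam, subfam_raw, sep = ".")
  tibble::tibble(sequence = labels, family = fam,
                 subfamily = match(sub_label, unique(sub_label)))
}

# connected components of the graph with edges where distance <= h
single_linkage_groups <- function(D, h) {
  n <- nrow(D)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (D[i, j] <= h + 1e-12 && comp[i] != comp[j]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

#' Find highly conserved alignment columns
#'
#' Conservation of a column is the proportion of its non-missing residues
#' equal to the modal residue; columns strictly above `threshold` are
#' flagged. Coordinates refer to the original alignment via the alignment's
#' `column_map`.
#'
#' @param aln a `cyp_alignment` (at least 2 sequences)
#' @param threshold flagging threshold, strict (default 0.95)
#' @return tibble with columns `column` (original 1-based), `conservation`,
#'   `modal_residue`, `flagged`; all-missing columns are skipped
#' @export
conserved_sites <- function(aln, threshold = 0.95) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  type <- aln_type(aln)
  mc <- missing_chars(type)
  cmap <- attr(aln, "column_map")
  m <- unclass(aln)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[!col %in% mc]
    if (length(col) == 0L) return(NULL)
    tab <- sort(table(col), decreasing = TRUE)
    cons <- tab[1] / length(col)
    orig <- if (type == "codon") j else cmap[j]
    tibble::tibble(column = orig, conservation = as.numeric(cons),
                   modal_residue = names(tab)[1],
                   flagged = as.numeric(cons) > threshold)
  })
  dplyr::bind_rows(res)
}

#' Find group-diagnostic alignment sites
#'
#' A site is diagnostic for a group when every non-missing member of the
#' group carries the same residue (or at least `within_threshold` of them
#' do) and no sequence outside the group carries that residue.
#'
#' @param aln a `cyp_alignment`
#' @param groups named character vector mapping sequence names to group
#'   labels; at least 2 non-empty groups
#' @param within_threshold required within-group frequency of the residue
#'   (default 1.0 = strict fixation)
#' @return tibble with columns `column` (original 1-based), `group`,
#'   `residue`, `within_freq`
#' @export
group_diagnostic_sites <- function(aln, groups, within_threshold = 1.0) {
  if (length(unique(groups)) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (!all(names(groups) %in% rownames(aln)))
    stop("group label(s) for unknown sequence(s)", call. = FALSE)
  mc <- missing_chars(aln_type(aln))
  cmap <- attr(aln, "column_map")
  m <- unclass(aln)
  out <- list()
  for (g in unique(groups)) {
    in_rows <- rownames(m) %in% names(groups)[groups == g]
    out_rows <- !in_rows
    for (j in seq_len(ncol(m))) {
      inside <- m[in_rows, j]
      inside <- inside[!inside %in% mc]
      if (length(inside) == 0L) next   # group all-missing: site skipped
      tab <- sort(table(inside), decreasing = TRUE)
      freq <- tab[1] / length(inside)
      if (freq < within_threshold - 1e-12) next
      res <- names(tab)[1]
      outside <- m[out_rows, j]
      outside <- outside[!outside %in% mc]
      if (res %in% outside) next
      out[[length(out) + 1L]] <- tibble::tibble(
        column = cmap[j], group = g, residue = res,
        within_freq = as.numeric(freq))
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(column = integer(), group = character(),
                          residue = character(), within_freq = numeric()))
  dplyr::arrange(dplyr::bind_rows(out), .data$column, .data$group)
}
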