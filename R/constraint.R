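# Functional-constraint estimation: synonymous and nonsynonymous
# substitutions placed on a fixed 4-taxon species tree by least squares,
# f = sum(bN)/sum(bS), and the B-vs-D group comparison.

#' Estimate functional constraint on a fixed species topology
#'
#' NG86 dN and dS distance matrices are computed for the gene's codon
#' alignment, OLS branch lengths are fitted independently to each on the
#' fixed topology (gene tree forced equal to the species tree; negative
#' lengths clamped to zero), and `f = sum(bN) / sum(bS)` over all branches.
#' The degree of functional constraint is `1 - f`.
#'
#' @param aln codon `cyp_alignment` of orthologs, one per species
#' @param topology fixed species tree (ape `phylo`) over the sequence names
#' @param policy a [site_filter_policy()]
#' @param gene gene label for the output row
#' @return one-row tibble: `gene`, `f`, `constraint`, `sum_bN`, `sum_bS`,
#'   `n_clamped`, `sse_N`, `sse_S`, plus list-columns `branches_N`,
#'   `branches_S`; `f` is `NA` with a warning when `sum(bS) = 0`
#' @export
estimate_f <- function(aln, topology, policy = site_filter_policy(),
                       gene = NA_character_) {
  both <- ng86_matrices(aln, policy)
  dN <- both$dN
  dS <- both$dS
  if (any(!is.finite(unclass(dN))) || any(!is.finite(unclass(dS))))
    stop("saturated or undefined NG86 distances for gene ", gene,
         call. = FALSE)
  fitN <- suppressWarnings(ols_branch_lengths(topology, dN))
  fitS <- suppressWarnings(ols_branch_lengths(topology, dS))
  sum_bN <- sum(fitN$lengths$length)
  sum_bS <- sum(fitS$lengths$length)
  f <- if (sum_bS > 0) sum_bN / sum_bS else {
    warning("sum of synonymous branch lengths is 0: f undefined for gene ",
            gene)
    NA_real_
  }
  tibble::tibble(gene = gene, f = f, constraint = 1 - f,
                 sum_bN = sum_bN, sum_bS = sum_bS,
                 n_clamped = fitN$n_clamped + fitS$n_clamped,
                 sse_N = fitN$sse, sse_S = fitS$sse,
                 branches_N = list(fitN$lengths),
                 branches_S = list(fitS$lengths))
}

#' Mann-Whitney U test
#'
#' U is computed from rank sums with midranks for ties. In `"exact"` mode
#' (no ties) the p-value uses the exact null distribution of U; in
#' `"normal"` mode a normal approximation with tie-corrected variance and
#' continuity correction is used. `"auto"` picks exact when there are no
#' ties and `n1 + n2 <= 20`.
#'
#' @param x,y numeric value sets (both nonempty)
#' @param mode `"auto"`, `"exact"` or `"normal"`
#' @return a `cyp_mwu` object (list with `U`, `p_value`, `method`, `n1`,
#'   `n2`, `degenerate`)
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact two-sided p = 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)   # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_v)
  has_ties <- any(ties > 1)
  degenerate <- length(ties) == 1L
  if (degenerate) {
    out <- list(U = U, p_value = 1, method = "degenerate (all values tied)",
                n1 = n1, n2 = n2, degenerate = TRUE)
    class(out) <- "cyp_mwu"
    return(out)
  }
  if (mode == "exact" && has_ties)
    stop("exact mode requires untied data", call. = FALSE)
  use_exact <- mode == "exact" ||
    (mode == "auto" && !has_ties && n1 + n2 <= 20)
  if (use_exact) {
    # two-sided exact p from the null distribution of U
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(p, 1)
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- U - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)  # continuity corr.
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(p, 1)
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  out <- list(U = U, p_value = p, method = method, n1 = n1, n2 = n2,
              degenerate = FALSE)
  class(out) <- "cyp_mwu"
  out
}

#' @export
print.cyp_mwu <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n",
      "U = ", x$U, ", n1 = ", x$n1, ", n2 = ", x$n2,
      ", two-sided p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Compare functional constraint between B- and D-type genes
#'
#' Summarises per-gene `f` values by type (mean, sd, median) and tests the
#' B-vs-D difference with the Mann-Whitney U test.
#'
#' @param f_values tibble with columns `gene`, `f` and either `cyp_type` or
#'   a `catalog` to join types from
#' @param catalog optional `cyp_catalog` supplying `cyp_type` by gene name
#' @param mode test mode for [mann_whitney_u()]
#' @return a `cyp_type_comparison` list: `summary` tibble (per type),
#'   `test` (`cyp_mwu`), `f_values`
#' @export
compare_types <- function(f_values, catalog = NULL,
                          mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  tab <- tibble::as_tibble(f_values)
  if (!"cyp_type" %in% names(tab)) {
    if (is.null(catalog))
      stop("f_values lacks cyp_type and no catalog supplied", call. = FALSE)
    tab <- dplyr::left_join(tab,
                            dplyr::select(tibble::as_tibble(catalog),
                                          gene = "name", "cyp_type"),
                            by = "gene")
  }
  tab <- dplyr::filter(tab, !is.na(.data$f), .data$cyp_type %in% c("B", "D"))
  fb <- tab$f[tab$cyp_type == "B"]
  fd <- tab$f[tab$cyp_type == "D"]
  if (length(fb) == 0L || length(fd) == 0L)
    stop("one of the B/D groups is empty", call. = FALSE)
  summary <- dplyr::summarise(
    dplyr::group_by(tab, .data$cyp_type),
    n = dplyr::n(), mean = mean(.data$f), sd = stats::sd(.data$f),
    median = stats::median(.data$f), .groups = "drop")
  test <- mann_whitney_u(fb, fd, mode = mode)
  structure(list(summary = summary, test = test, f_values = tab),
            class = "cyp_type_comparison")
}

#' @export
print.cyp_type_comparison <- function(x, ...) {
  cat("<B vs D functional-constraint comparison>\n")
  print(x$summary)
  print(x$test)
  invisible(x)
}
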