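# Molecular-clock dating: duplication nodes by branch-length ratios against
# a species calibration, and pseudogenization events from the excess dN/dS
# accumulated during the neutral (post-inactivation) period.

#' Date a duplication node by branch-length ratios
#'
#' Under a molecular clock, the path length from the duplication node to a
#' calibration node (`b_pre`) and from the calibration node to a tip
#' (`b_post`, corresponding to `t_cal` myr) give the duplication-time
#' estimate `t_cal * (b_pre + b_post) / b_post` per tip lineage. All
#' per-lineage estimates, their range and the conservative minimum are
#' reported.
#'
#' @param tree ape `phylo` with branch lengths (substitutions/site)
#' @param dup_node duplication node (number, or character label of a tip
#'   pair MRCA via `mrca_node()`)
#' @param cal_nodes calibration node number(s); each must be a descendant of
#'   `dup_node`
#' @param t_cal calibration age in mya for the species split at each
#'   calibration node
#' @param tips optional character vector restricting which tips are used as
#'   lineages (default: all tips descending from each calibration node)
#' @return a `cyp_duplication_dating` list: `estimates` tibble (lineage,
#'   cal_node, b_pre, b_post, estimate), `minimum`, `range`, `t_cal`
#' @export
duplication_time <- function(tree, dup_node, cal_nodes, t_cal, tips = NULL) {
  stopifnot(t_cal > 0)
  nd <- ape::dist.nodes(tree)
  ntip <- ape::Ntip(tree)
  rows <- list()
  for (cal in cal_nodes) {
    if (cal == dup_node)
      stop("calibration node must differ from the duplication node",
           call. = FALSE)
    b_pre <- nd[dup_node, cal]
    cal_tips <- if (cal <= ntip) cal else
      node_tip_descendants(tree)[[cal]]
    labels <- tree$tip.label[cal_tips]
    if (!is.null(tips)) {
      cal_tips <- cal_tips[labels %in% tips]
      labels <- tree$tip.label[cal_tips]
    }
    for (k in seq_along(cal_tips)) {
      b_post <- nd[cal, cal_tips[k]]
      if (b_post == 0) {
        warning("lineage ", labels[k], " dropped: zero post-calibration ",
                "branch length")
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        lineage = labels[k], cal_node = as.integer(cal),
        b_pre = b_pre, b_post = b_post,
        estimate = t_cal * (b_pre + b_post) / b_post)
    }
  }
  est <- dplyr::bind_rows(rows)
  if (nrow(est) == 0L)
    stop("all lineages dropped: no duplication-time estimate", call. = FALSE)
  structure(list(estimates = est,
                 minimum = min(est$estimate),
                 range = range(est$estimate),
                 t_cal = t_cal),
            class = "cyp_duplication_dating")
}

#' @export
print.cyp_duplication_dating <- function(x, ...) {
  cat("<duplication dating> ", nrow(x$estimates), " lineage estimate(s), ",
      "range ", round(x$range[1], 1), "-", round(x$range[2], 1),
      " mya; conservative (minimum) estimate ", round(x$minimum, 1),
      " mya (calibration ", x$t_cal, " mya)\n", sep = "")
  invisible(x)
}

#' MRCA node number of a set of tips
#' @param tree ape `phylo`
#' @param tips character vector of tip labels
#' @return internal node number
#' @export
mrca_node <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label(s)", call. = FALSE)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Date a pseudogenization event from the dN/dS mixture
#'
#' For a pseudogene compared with a functional ortholog that diverged `T`
#' mya, nonsynonymous substitutions accrued at `f` times the synonymous
#' rate while the gene was functional (duration `2T - t` along the two
#' lineages) and at the full synonymous rate after inactivation (duration
#' `t`), while synonymous substitutions accrued at the synonymous rate
#' throughout. The observed ratio `R = dN/dS` therefore satisfies
#' `R = f + (1 - f) * t / (2T)`, giving `t = 2T (R - f) / (1 - f)`.
#' Estimates outside `[0, T]` are clamped and flagged.
#'
#' @param R observed dN/dS of the pseudogene/functional-ortholog pair
#' @param f dN/dS of functional-lineage evolution (0 <= f < 1); typically
#'   estimated from functional ortholog pairs of the same family over the
#'   same species pair
#' @param T_div divergence time of the pair in mya
#' @return a `cyp_pseudo_dating` tibble: `R`, `f`, `T_div`, `t_raw`, `t`
#'   (clamped to `[0, T_div]`), `clamped`
#' @examples
#' pseudogenization_time(R = 0.4, f = 0.2, T_div = 10) # t = 5 mya
#' @export
pseudogenization_time <- function(R, f, T_div) {
  if (any(!is.finite(R))) stop("R undefined (dS = 0?)", call. = FALSE)
  if (any(f >= 1)) stop("f must be < 1", call. = FALSE)
  if (any(f < 0) || any(R < 0)) stop("R and f must be nonnegative",
                                     call. = FALSE)
  if (any(T_div <= 0)) stop("divergence time must be positive", call. = FALSE)
  t_raw <- 2 * T_div * (R - f) / (1 - f)
  t <- pmin(pmax(t_raw, 0), T_div)
  out <- tibble::tibble(R = R, f = f, T_div = T_div, t_raw = t_raw, t = t,
                        clamped = t_raw < 0 | t_raw > T_div)
  class(out) <- c("cyp_pseudo_dating", class(out))
  out
}

#' dN/dS ratio of a codon sequence pair
#'
#' @inheritParams ng86_pair
#' @return `R = dN/dS`; `NA` with a warning when `dS = 0` (undefined)
#' @export
pair_ratio <- function(a, b, policy = site_filter_policy(),
                       correction = c("jukes_cantor", "none")) {
  res <- ng86_pair(a, b, policy, correction = match.arg(correction))
  if (!isTRUE(res$dS > 0)) {
    warning("dS = 0: dN/dS undefined")
    return(NA_real_)
  }
  res$dN / res$dS
}

#' Date a duplication from a codon alignment of the two duplicate clades
#'
#' Computes Jukes-Cantor-corrected distances, fits OLS branch lengths on
#' the fixed topology, places the duplication node at the midpoint of the
#' branch separating the two duplicate clades (the clock assumption), and
#' applies [duplication_time()] with the species calibration split of each
#' clade.
#'
#' @param aln codon `cyp_alignment` whose sequence names are the tips of
#'   `topology`
#' @param topology fixed ape `phylo` over the same tips
#' @param side_a,side_b tip labels of the two duplicate clades
#' @param t_cal calibration age (mya) of the species split within each
#'   clade
#' @param method distance method for [distance_matrix()] (default `"p"`,
#'   i.e. total nucleotide differences, JC-corrected)
#' @param policy a [site_filter_policy()]
#' @return a `cyp_duplication_dating` (see [duplication_time()])
#' @export
duplication_time_from_alignment <- function(aln, topology, side_a, side_b,
                                            t_cal, method = "p",
                                            policy = site_filter_policy()) {
  D <- distance_matrix(aln, method, policy, correction = "jukes_cantor")
  fit <- suppressWarnings(ols_branch_lengths(topology, D))
  rooted <- root_with_outgroup(fit$tree, side_a)
  dup <- ape::Ntip(rooted) + 1L
  cal_a <- mrca_node(rooted, side_a)
  cal_b <- mrca_node(rooted, side_b)
  duplication_time(rooted, dup, c(cal_a, cal_b), t_cal)
}

#' Bootstrap interval for a duplication date
#'
#' Nonparametric bootstrap over alignment columns: codon columns are
#' resampled, distances and OLS branch lengths refitted, and the
#' conservative (minimum) estimate recomputed per replicate. This interval
#' estimator is the package's own choice of uncertainty measure.
#'
#' @inheritParams duplication_time_from_alignment
#' @param n_reps bootstrap replicates (default 200)
#' @param seed integer seed
#' @return tibble: `estimate` (point, full data), `lower`, `upper` (2.5/97.5
#'   percentiles), `sd`, `n_reps`
#' @export
duplication_time_bootstrap <- function(aln, topology, side_a, side_b, t_cal,
                                       n_reps = 200, seed = 1, method = "p",
                                       policy = site_filter_policy()) {
  point <- duplication_time_from_alignment(aln, topology, side_a, side_b,
                                           t_cal, method, policy)$minimum
  nu <- n_units(aln, aln_type(aln))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  vals <- vapply(seq_len(n_reps), function(r) {
    idx <- sample.int(nu, nu, replace = TRUE)
    tryCatch(duplication_time_from_alignment(subset_units(aln, idx),
                                             topology, side_a, side_b,
                                             t_cal, method, policy)$minimum,
             error = function(e) NA_real_)
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  tibble::tibble(estimate = point,
                 lower = stats::quantile(vals, 0.025, names = FALSE),
                 upper = stats::quantile(vals, 0.975, names = FALSE),
                 sd = stats::sd(vals), n_reps = length(vals))
}
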