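primate_topo <- function() {
  ape::read.tree(text = "(((Hosa:6.7,Patr:6.7):22.3,Mamu:29):14,Caja:43);")
}

test_that("estimate_f degenerate matrices give f = 1 and f = 0", {
  topo <- primate_topo()
  D <- matrix(0.1, 4, 4,
              dimnames = list(topo$tip.label, topo$tip.label))
  diag(D) <- 0
  # identical dN and dS matrices: f = 1
  fitN <- ols_branch_lengths(topo, D)
  fitS <- ols_branch_lengths(topo, D)
  expect_equal(sum(fitN$lengths$length) / sum(fitS$lengths$length), 1)
  expect_gt(sum(fitS$lengths$length), 0)

  # an alignment with only a few synonymous differences: f = 0
  # TTT<->TTC (Phe synonymous third-position change)
  mostly <- function(k) paste0(strrep("TTC", k), strrep("TTT", 50 - k))
  aln <- new_alignment(c(Hosa = mostly(0), Patr = mostly(3),
                         Mamu = mostly(5), Caja = mostly(8)), "codon")
  res <- estimate_f(aln, topo, gene = "syn_only")
  expect_equal(res$f, 0)
  expect_equal(res$constraint, 1)

  # no synonymous divergence at all: f undefined with warning
  aln0 <- new_alignment(c(Hosa = strrep("TTT", 30), Patr = strrep("TTT", 30),
                          Mamu = strrep("TTT", 30), Caja = strrep("TTT", 30)),
                        "codon")
  expect_warning(res0 <- estimate_f(aln0, topo, gene = "flat"), "undefined")
  expect_true(is.na(res0$f))
})

test_that("estimate_f is invariant to sequence input order", {
  topo <- primate_topo()
  sc <- sim_config(seed = 81, r_s = 0.0015, f_functional = 0.3,
                   n_codons = 800)
  s <- simulate_codon_sequences(topo, sc)
  aln <- s$alignment
  perm <- unclass(aln)[c(3, 1, 4, 2), ]
  aln2 <- new_alignment(perm, "codon")
  f1 <- suppressWarnings(estimate_f(aln, topo)$f)
  f2 <- suppressWarnings(estimate_f(aln2, topo)$f)
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("estimate_f recovers the simulating constraint", {
  topo <- primate_topo()
  fs <- vapply(1:40, function(i) {
    sc <- sim_config(seed = 8100 + i, r_s = 0.0015, f_functional = 0.2,
                     n_codons = 2000)
    s <- simulate_codon_sequences(topo, sc)
    suppressWarnings(estimate_f(s$alignment, topo)$f)
  }, numeric(1))
  expect_lt(abs(mean(fs) - 0.2), 0.05)
})

test_that("Mann-Whitney U matches the worked example and enumeration oracle", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)

  set.seed(82)
  for (n1 in 1:6) for (n2 in n1:(12 - n1)) {
    x <- stats::rnorm(n1)
    y <- stats::rnorm(n2)
    got <- mann_whitney_u(x, y, mode = "exact")
    expect_equal(got$p_value, oracle_mwu_exact(x, y), tolerance = 1e-12,
                 label = paste(n1, n2))
  }
})

test_that("U statistics are complementary and identical sets give p = 1", {
  set.seed(83)
  x <- stats::rnorm(8); y <- stats::rnorm(5)
  expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U,
               length(x) * length(y))
  same <- c(2, 5, 9)
  expect_equal(mann_whitney_u(same, same)$p_value, 1)
  deg <- mann_whitney_u(rep(1, 4), rep(1, 6))
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
})

test_that("exact and normal modes agree closely at n1 = n2 = 10", {
  set.seed(84)
  x <- stats::rnorm(10); y <- stats::rnorm(10, 0.4)
  pe <- mann_whitney_u(x, y, mode = "exact")$p_value
  pn <- mann_whitney_u(x, y, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.02)
})

test_that("test power at a 0.1 shift exceeds one half", {
  set.seed(85)
  rej <- 0L
  for (i in 1:500) {
    x <- stats::rnorm(22, 0.24, 0.13)
    y <- stats::rnorm(35, 0.34, 0.13)
    if (mann_whitney_u(x, y, mode = "normal")$p_value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 500, 0.5)
})

test_that("compare_types summarises and tests groups", {
  f_tbl <- tibble::tibble(
    gene = paste0("g", 1:10),
    cyp_type = rep(c("B", "D"), each = 5),
    f = c(0.1, 0.15, 0.2, 0.22, 0.25, 0.3, 0.31, 0.35, 0.4, 0.42))
  cmp <- compare_types(f_tbl)
  expect_s3_class(cmp, "cyp_type_comparison")
  med <- cmp$summary$median
  expect_lt(med[cmp$summary$cyp_type == "B"],
            med[cmp$summary$cyp_type == "D"])
  expect_lt(cmp$test$p_value, 0.05)

  # identical groups: medians equal, p = 1
  flat <- tibble::tibble(gene = paste0("g", 1:6),
                         cyp_type = rep(c("B", "D"), 3), f = 0.2)
  cmp_flat <- compare_types(flat)
  expect_equal(cmp_flat$test$p_value, 1)

  # single gene per group: summary defined, exact p = 1
  tiny <- tibble::tibble(gene = c("a", "b"), cyp_type = c("B", "D"),
                         f = c(0.1, 0.2))
  cmp_tiny <- compare_types(tiny)
  expect_equal(cmp_tiny$test$p_value, 1)

  # empty group errors; catalog join works
  expect_error(compare_types(dplyr::filter(f_tbl, cyp_type == "B")), "empty")
  cat_tbl <- cyp_human_catalog()
  withcat <- tibble::tibble(gene = c("CYP1A1", "CYP7A1"), f = c(0.3, 0.2))
  expect_s3_class(compare_types(withcat, catalog = cat_tbl),
                  "cyp_type_comparison")
})

test_that("tidiers and autoplot return well-formed objects", {
  f_tbl <- tibble::tibble(gene = paste0("g", 1:8),
                          cyp_type = rep(c("B", "D"), each = 4),
                          f = c(0.1, 0.2, 0.15, 0.22, 0.3, 0.35, 0.31, 0.4))
  cmp <- compare_types(f_tbl)
  expect_s3_class(tidy(cmp), "tbl_df")
  gl <- glance(cmp)
  expect_true(all(c("U", "p_value", "median_B", "median_D") %in% names(gl)))
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})
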