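test_that("assign_type uses the smallest unanimous supported clade", {
  tr <- ape::read.tree(text = "(((q1:1,refD1:1)96:1,refD2:1)99:1,(refB1:1,refB2:1)97:2);")
  refs <- c(refD1 = "D", refD2 = "D", refB1 = "B", refB2 = "B")
  res <- assign_type(tr, refs, min_support = 80)
  expect_identical(res$type[res$leaf == "q1"], "D")
  expect_identical(res$support[res$leaf == "q1"], 96)
})

test_that("queries in mixed or unsupported clades are unassigned", {
  # every supported clade containing q mixes B and D references
  tr <- ape::read.tree(text = "((q:1,refB1:1)40:1,(refD1:1,refB2:1)95:1);")
  res <- assign_type(tr, c(refB1 = "B", refB2 = "B", refD1 = "D"),
                     min_support = 80)
  expect_identical(res$type[res$leaf == "q"], "unassigned")
  expect_error(assign_type(tr, c(refB1 = "B", refB2 = "B")), "each type")
})

test_that("assign_type is stable under unsupported extra structure", {
  flat <- ape::read.tree(text = "(((q:1,refD1:1)96:1,refD2:1)99:1,refB1:3);")
  nested <- ape::read.tree(text = "((((q:1,refD1:1)50:0,refD2:1)96:1,refD2b:1)99:1,refB1:3);")
  refs1 <- c(refD1 = "D", refD2 = "D", refB1 = "B")
  refs2 <- c(refD1 = "D", refD2 = "D", refD2b = "D", refB1 = "B")
  r1 <- assign_type(flat, refs1, 80)
  r2 <- assign_type(nested, refs2, 80)
  expect_identical(r1$type[r1$leaf == "q"], "D")
  expect_identical(r2$type[r2$leaf == "q"], "D")
})

test_that("assign_type recovers simulated two-family labels perfectly", {
  # two clades diverged long ago; one B-labeled, one D-labeled ancestor
  tr <- ape::read.tree(text = paste0(
    "((b1:10,(b2:6,b3:6):4):80,(d1:10,(d2:6,d3:6):4):80);"))
  sc <- sim_config(seed = 52, r_s = 0.002, f_functional = 0.4,
                   n_codons = 600)
  s <- simulate_codon_sequences(tr, sc)
  bs <- bootstrap_support(s$alignment, function(a) distance_matrix(a, "p"),
                          n_reps = 100, seed = 9)
  rooted <- root_with_outgroup(bs, c("b1", "b2", "b3"))
  # transfer node labels (support) through rooting
  refs <- c(b1 = "B", d1 = "D")
  res <- assign_type(rooted, refs, min_support = 80)
  got <- res$type[match(c("b2", "b3", "d2", "d3"), res$leaf)]
  expect_identical(got, c("B", "B", "D", "D"))
})

test_that("identity clustering chains families and nests subfamilies", {
  # identities: a-b 0.6, b-c 0.5, a-c 0.3 -> one family by chaining
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 60), strrep("R", 40))
  c_ <- paste0(strrep("N", 40), strrep("A", 30), strrep("R", 30))
  expect_equal(identity_fraction(a, b), 0.6)
  expect_equal(identity_fraction(b, c_), 0.5)
  expect_equal(identity_fraction(a, c_), 0.3)
  aln <- new_alignment(c(a = a, b = b, c = c_), "protein")
  res <- assign_family_by_identity(aln)
  expect_identical(length(unique(res$family)), 1L)

  # identical sequences: same family and subfamily
  aln2 <- new_alignment(c(x = a, y = a), "protein")
  res2 <- assign_family_by_identity(aln2)
  expect_identical(res2$subfamily[1], res2$subfamily[2])

  # identity exactly 0.50: same family, different subfamilies
  half <- paste0(strrep("A", 50), strrep("L", 50))
  aln3 <- new_alignment(c(p = a, q = half), "protein")
  res3 <- assign_family_by_identity(aln3)
  expect_identical(res3$family[1], res3$family[2])
  expect_false(res3$subfamily[1] == res3$subfamily[2])
})

test_that("subfamily clusters always nest within family clusters", {
  set.seed(53)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  m <- matrix(sample(aa, 8 * 60, replace = TRUE), 8, 60,
              dimnames = list(paste0("s", 1:8), NULL))
  m[2, ] <- m[1, ]; m[2, 1:20] <- sample(aa, 20, replace = TRUE)
  m[4, ] <- m[3, ]; m[4, 1:10] <- sample(aa, 10, replace = TRUE)
  res <- assign_family_by_identity(new_alignment(m, "protein"))
  nesting <- unique(res[, c("family", "subfamily")])
  expect_identical(anyDuplicated(nesting$subfamily), 0L)
})

test_that("conserved_sites flags strictly above threshold with original coords", {
  m <- matrix("C", 20, 3)
  m[1, 2] <- "W"          # 19/20 = 0.95, not flagged under strict rule
  m[1:2, 3] <- c("W", "Y") # 18/20 = 0.90
  rownames(m) <- paste0("s", 1:20)
  aln <- new_alignment(m, "protein")
  res <- conserved_sites(aln, threshold = 0.95)
  expect_true(res$flagged[res$column == 1])
  expect_false(res$flagged[res$column == 2])
  expect_equal(res$conservation[res$column == 2], 0.95)

  # planted invariant columns are exactly recovered after gap filtering
  set.seed(54)
  aa <- c("A", "R", "N", "D", "C")
  big <- matrix(sample(aa, 12 * 30, replace = TRUE), 12, 30,
                dimnames = list(paste0("s", 1:12), NULL))
  planted <- c(4L, 11L, 19L, 28L)
  for (j in planted) big[, j] <- "H"
  for (j in setdiff(seq_len(30), planted)) {
    big[seq_len(6), j] <- sample(aa, 6, replace = TRUE)
    big[7:12, j] <- sample(setdiff(aa, big[1, j]), 6, replace = TRUE)
  }
  res2 <- conserved_sites(new_alignment(big, "protein"), threshold = 0.95)
  expect_identical(res2$column[res2$flagged], planted)
})

test_that("conservation threshold endpoints behave as specified", {
  m <- matrix(c("A", "A", "A", "R"), 4, 1,
              dimnames = list(paste0("s", 1:4), NULL))
  aln <- new_alignment(m, "protein")
  expect_true(conserved_sites(aln, threshold = 0)$flagged)
  expect_false(conserved_sites(aln, threshold = 1)$flagged)
})

test_that("group-diagnostic sites require fixation inside, absence outside", {
  m <- rbind(x1 = c("F", "F", "L"),
             x2 = c("F", "F", "F"),
             y1 = c("V", "F", "V"),
             y2 = c("V", "-", "V"))
  aln <- new_alignment(m, "protein")
  groups <- c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y")
  res <- group_diagnostic_sites(aln, groups)
  # col 1 diagnostic for both groups; col 2 shared residue -> neither;
  # col 3 X not fixed (F/L), Y fixed V absent from X -> Y only
  expect_setequal(res$group[res$column == 1], c("X", "Y"))
  expect_identical(res$group[res$column == 2], character(0))
  expect_identical(res$group[res$column == 3], "Y")
  # symmetric under relabeling
  flipped <- c(x1 = "Y", x2 = "Y", y1 = "X", y2 = "X")
  res2 <- group_diagnostic_sites(aln, flipped)
  expect_identical(nrow(res), nrow(res2))
  expect_error(group_diagnostic_sites(aln, c(x1 = "X", x2 = "X")), "2 groups")
})

test_that("planted clan-diagnostic residues are exactly recovered", {
  set.seed(55)
  aa <- c("A", "R", "N", "D")
  m <- matrix(sample(aa, 9 * 40, replace = TRUE), 9, 40,
              dimnames = list(paste0("s", 1:9), NULL))
  groups <- stats::setNames(rep(c("g1", "g2", "g3"), each = 3), rownames(m))
  m[, 7] <- c(rep("W", 3), sample(aa, 6, replace = TRUE))
  m[, 23] <- c(sample(aa, 3, replace = TRUE), rep("Y", 3),
               sample(aa, 3, replace = TRUE))
  res <- group_diagnostic_sites(new_alignment(m, "protein"), groups)
  expect_true(any(res$column == 7 & res$group == "g1" & res$residue == "W"))
  expect_true(any(res$column == 23 & res$group == "g2" & res$residue == "Y"))
})
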