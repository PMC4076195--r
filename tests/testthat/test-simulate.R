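test_that("gene-content simulation is deterministic and silent at zero rates", {
  tr <- cyp_vertebrate_chronogram()
  cfg <- sim_config(seed = 91, gain_rate = 0, loss_rate = 0, pseudo_rate = 0,
                    n_root_genes = 5)
  sim <- simulate_gene_content(tr, cfg)
  expect_true(all(sim$matrix == 1L))
  expect_identical(nrow(sim$truth), 0L)

  cfg2 <- sim_config(seed = 92, gain_rate = 1, loss_rate = 0.5,
                     pseudo_rate = 0.2, n_root_genes = 3)
  a <- simulate_gene_content(tr, cfg2)
  b <- simulate_gene_content(tr, cfg2)
  expect_identical(a, b)
})

test_that("explosive settings are refused", {
  tr <- cyp_vertebrate_chronogram()
  expect_error(simulate_gene_content(tr, sim_config(seed = 1, gain_rate = 300,
                                                    loss_rate = 0,
                                                    n_root_genes = 100)),
               "explosive")
})

test_that("root-lineage gains are Poisson with mean rate x length / 100", {
  # gains never terminate the producing lineage, so the root lineage's own
  # gain count over the whole tree is an exact Poisson marking
  tr <- cyp_vertebrate_chronogram()
  lambda <- 0.7 * 2685 / 100
  n_rep <- 400L
  cnts <- vapply(seq_len(n_rep), function(i) {
    s <- simulate_gene_content(tr, sim_config(seed = 9000 + i,
                                              gain_rate = 0.7, loss_rate = 0,
                                              pseudo_rate = 0,
                                              n_root_genes = 1))
    sum(s$truth$type == "gain" & s$truth$lineage == 1L)
  }, numeric(1))
  expect_lt(abs(mean(cnts) - lambda),
            3 * stats::sd(cnts) / sqrt(n_rep) + 1e-9)
  # chi-square GOF against the Poisson pmf (binned tails)
  brk <- c(-Inf, seq(lambda - 8, lambda + 8, by = 2), Inf)
  obs <- table(cut(cnts, brk))
  pp <- diff(stats::ppois(c(-1, seq(lambda - 8, lambda + 8, by = 2), Inf),
                          lambda))
  keep <- pp * n_rep >= 5
  chi <- sum((as.numeric(obs[keep]) - n_rep * pp[keep])^2 /
               (n_rep * pp[keep]))
  expect_lt(chi, stats::qchisq(0.99, sum(keep) - 1))
})

test_that("loss counts match the analytic survival-recursion expectation", {
  # for a single lineage with only losses, the expected number of loss
  # events is sum over branches of P(alive at branch start) * P(loss on
  # branch), computable exactly by recursion
  tr <- cyp_vertebrate_chronogram()
  rate <- 2 / 100
  ages <- node_ages(tr)
  root <- ape::Ntip(tr) + 1L
  expected_losses <- function(node, p_alive) {
    tot <- 0
    for (ch in tr$edge[tr$edge[, 1] == node, 2]) {
      dur <- ages[node] - ages[ch]
      p_loss <- 1 - exp(-rate * dur)
      tot <- tot + p_alive * p_loss
      if (ch > ape::Ntip(tr))
        tot <- tot + expected_losses(ch, p_alive * (1 - p_loss))
    }
    tot
  }
  want <- expected_losses(root, 1)
  n_rep <- 400L
  cnts <- vapply(seq_len(n_rep), function(i) {
    s <- simulate_gene_content(tr, sim_config(seed = 9500 + i, gain_rate = 0,
                                              loss_rate = 2, pseudo_rate = 0,
                                              n_root_genes = 1))
    sum(s$truth$type == "loss")
  }, numeric(1))
  expect_lt(abs(mean(cnts) - want), 3 * stats::sd(cnts) / sqrt(n_rep))
})

test_that("codon simulation limits: f = 0 gives dN = 0; same seed bit-identical", {
  tr <- ape::read.tree(text = "(a:30,b:30);")
  s0 <- simulate_codon_sequences(tr, sim_config(seed = 93, r_s = 0.003,
                                                f_functional = 0,
                                                n_codons = 1500))
  res <- ng86_pair(unclass(s0$alignment)["a", ], unclass(s0$alignment)["b", ])
  # pathway averaging can assign fractional Nd to multi-hit codons even
  # when every accepted change was synonymous; dN stays near zero
  expect_gt(res$Sd, 0)
  expect_lt(res$Nd / res$Sd, 0.05)
  expect_lt(res$dN, 0.01)

  cfg <- sim_config(seed = 94, r_s = 0.003, f_functional = 0.5,
                    n_codons = 400)
  s1 <- simulate_codon_sequences(tr, cfg)
  s2 <- simulate_codon_sequences(tr, cfg)
  expect_identical(unclass(s1$alignment)[, ], unclass(s2$alignment)[, ])
})

test_that("functional-regime sequences never contain internal stops", {
  tr <- cyp_vertebrate_chronogram()
  s <- simulate_codon_sequences(tr, sim_config(seed = 95, r_s = 0.004,
                                               f_functional = 0.6,
                                               n_codons = 300))
  m <- unclass(s$alignment)
  for (i in seq_len(nrow(m))) {
    cods <- apply(matrix(m[i, ], nrow = 3), 2, paste, collapse = "")
    expect_false(any(cods %in% c("TAA", "TAG", "TGA")),
                 label = rownames(m)[i])
  }
})

test_that("synonymous divergence grows linearly with path duration", {
  ds <- vapply(seq(5, 50, by = 5), function(Tm) {
    tr <- ape::read.tree(text = sprintf("(a:%d,b:%d);", Tm, Tm))
    s <- simulate_codon_sequences(tr, sim_config(seed = 96 + Tm,
                                                 r_s = 0.002,
                                                 f_functional = 0.3,
                                                 n_codons = 10000))
    ng86_pair(unclass(s$alignment)["a", ], unclass(s$alignment)["b", ])$dS
  }, numeric(1))
  fit <- stats::lm(ds ~ seq(5, 50, by = 5))
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("regime switch to neutrality is recovered by the dating estimator", {
  ests <- vapply(1:30, function(i) {
    tr <- ape::read.tree(text = "(F:10,P:10);")
    reg <- data.frame(node = "P", offset = 4, f = 1)
    sc <- sim_config(seed = 9700 + i, r_s = 0.005, f_functional = 0.25,
                     n_codons = 3000)
    s <- simulate_codon_sequences(tr, sc, regimes = reg)
    R <- suppressWarnings(
      pair_ratio(unclass(s$alignment)["F", ], unclass(s$alignment)["P", ]))
    pseudogenization_time(R, 0.25, 10)$t
  }, numeric(1))
  expect_lt(abs(mean(ests) - 6), 1)
})

test_that("duplication scenario exposes clock-proportional truth", {
  sc <- sim_config(seed = 98, r_s = 5e-4, f_functional = 0.5, n_codons = 200)
  sim <- simulate_duplication_scenario(800, 400, sc)
  expect_equal(sim$truth$expected_ratio, 1)
  expect_identical(sort(rownames(sim$alignment)),
                   sort(c("A_X", "A_Z", "B_X", "B_Z")))
  # degenerate limit: duplication just above the calibration
  sim2 <- simulate_duplication_scenario(400.1, 400,
                                        sim_config(seed = 99, r_s = 5e-4,
                                                   n_codons = 200))
  expect_equal(sim2$truth$expected_ratio, 0.1 / 400, tolerance = 1e-9)
})
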