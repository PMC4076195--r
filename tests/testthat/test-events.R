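chron3 <- function() as_chronogram(ape::read.tree(text = "((H:6,M:6):4,Z:10);"))

test_that("Dollo places a single gain at the MRCA and minimal losses", {
  tr <- chron3()
  # present in all leaves: 1 gain at root
  rec <- dollo_reconstruct(matrix(1L, 1, 3, dimnames = list("g", c("H", "M", "Z"))), tr)
  expect_identical(nrow(rec$events), 1L)
  expect_identical(rec$events$type, "gain")
  expect_identical(rec$events$node, ape::Ntip(tr) + 1L)

  # present in a single leaf: gain on that pendant branch
  rec1 <- dollo_reconstruct(matrix(c(0L, 1L, 0L), 1,
                                   dimnames = list("g", c("H", "M", "Z"))), tr)
  expect_identical(rec1$events$type, "gain")
  expect_identical(rec1$events$branch_label, "M")

  # present in H and Z only: gain at root + loss on M, 2 events
  rec2 <- dollo_reconstruct(matrix(c(1L, 0L, 1L), 1,
                                   dimnames = list("g", c("H", "M", "Z"))), tr)
  expect_identical(nrow(rec2$events), 2L)
  expect_setequal(rec2$events$type, c("gain", "loss"))
  expect_identical(rec2$events$branch_label[rec2$events$type == "loss"], "M")

  # all-absent group skipped with warning
  expect_warning(
    rec3 <- dollo_reconstruct(matrix(0L, 1, 3,
                                     dimnames = list("g", c("H", "M", "Z"))), tr),
    "absent")
  expect_identical(nrow(rec3$events), 0L)
})

test_that("copy-number changes become unit events placed towards the tips", {
  tr <- chron3()
  # two copies in H only: shared gain at root impossible without extra loss;
  # late placement puts the duplication on the H pendant branch
  rec <- dollo_reconstruct(matrix(c(2L, 1L, 1L), 1,
                                  dimnames = list("g", c("H", "M", "Z"))), tr)
  expect_identical(count_events(rec, "gain"), 2L)  # origin + H duplication
  gains <- rec$events[rec$events$type == "gain", ]
  expect_true("H" %in% gains$branch_label)
})

test_that("Dollo equals the exhaustive minimal-event oracle", {
  set.seed(61)
  for (i in 1:50) {
    n <- sample(4:6, 1)
    tr <- random_chronogram(n)
    counts <- stats::setNames(sample(0:2, n, replace = TRUE,
                                     prob = c(.3, .5, .2)), tr$tip.label)
    if (all(counts == 0)) counts[1] <- 1L
    m <- matrix(as.integer(counts), 1, dimnames = list("g", names(counts)))
    rec <- suppressWarnings(dollo_reconstruct(m, tr))
    expect_identical(nrow(rec$events),
                     as.integer(brute_force_min_events(counts, tr)),
                     label = paste("instance", i))
  }
})

test_that("brute force handles trivial rows and refuses large trees", {
  tr <- chron3()
  expect_identical(brute_force_min_events(c(H = 1L, M = 1L, Z = 1L), tr), 1L)
  expect_identical(brute_force_min_events(c(H = 0L, M = 1L, Z = 0L), tr), 1L)
  big <- random_chronogram(9)
  expect_error(brute_force_min_events(stats::setNames(rep(1L, 9),
                                                      big$tip.label), big),
               "8 species")
})

test_that("low-rate simulated gene content is reconstructed exactly", {
  tr <- cyp_vertebrate_chronogram()
  ok <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    sim <- simulate_gene_content(tr, sim_config(seed = 7000 + i,
                                                gain_rate = 0.01,
                                                loss_rate = 0.01,
                                                pseudo_rate = 0,
                                                n_root_genes = 1))
    if (all(sim$matrix == 0)) { ok <- ok + 1L; next }  # lost before any leaf
    rec <- suppressWarnings(dollo_reconstruct(sim$matrix, tr))
    true_n <- nrow(sim$truth) + 1L  # + root origin, not an event in truth
    if (nrow(rec$events) == true_n) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})

test_that("event counting filters and validates types", {
  ev <- cyp_btype_events()
  expect_identical(count_events(ev, "gain"), 19L)
  expect_identical(count_events(ev, "loss"), 16L)
  expect_identical(count_events(ev, "pseudogenization"), 5L)
  expect_identical(count_events(ev, "loss", branch = "Orla"), 3L)
  expect_identical(count_events(ev[0, ]), 0L)
  expect_error(count_events(ev, "duplication"), "unknown event type")
})

test_that("event rates are linear in counts and inverse-linear in window", {
  expect_equal(event_rate(19, 2685), 100 * 19 / 2685)
  expect_equal(event_rate(0, 50), 0)
  expect_error(event_rate(3, 0), "positive")
  expect_equal(event_rate(100 * 7, 2685), 100 * event_rate(7, 2685))
  expect_equal(event_rate(7, 2685 / 2), 2 * event_rate(7, 2685))
})

test_that("pseudogenization placement uses MRCA or pendant branch", {
  tr <- chron3()
  single <- place_pseudogenization(tr, "H", group = "CYP21A1P")
  expect_identical(single$branch_label, "H")
  shared <- place_pseudogenization(tr, c("H", "M"), group = "CYP2G1P")
  expect_identical(shared$node, ape::Ntip(tr) + 2L)
  expect_error(place_pseudogenization(tr, "nope"), "unknown")
})

test_that("presence/absence and event TSV round-trips", {
  m <- matrix(c(1L, 0L, 2L, 1L, 1L, 0L), 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("H", "M", "Z")))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_presence_absence(m, tmp)
  expect_identical(read_presence_absence(tmp), m)
  ev <- cyp_btype_events()
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, tmp2)
  expect_identical(as.data.frame(read_events(tmp2)), as.data.frame(ev))
})
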