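# Seeded simulators of the generative processes the analysis assumes:
# gene gain/loss/pseudogenization as Poisson events on chronogram branches,
# and codon sequences evolving with a clock-like synonymous rate and an
# acceptance probability f for nonsynonymous changes that jumps to 1 after
# pseudogenization.

#' Simulation configuration
#'
#' Defaults are the study conditions of the B-type gene analysis: gain,
#' loss and pseudogenization rates of 0.7, 0.6 and 0.19 events per 100 myr
#' per gene lineage, 22 root gene lineages, functional-lineage dN/dS
#' `f_functional = 0.24`, and a synonymous rate of 0.002 substitutions per
#' synonymous site per myr (a typical vertebrate nuclear value).
#'
#' @param seed integer master seed; per-stage streams are derived from it
#'   by a counter scheme so adding a stage does not shift other stages'
#'   draws
#' @param gain_rate,loss_rate,pseudo_rate events per 100 myr per lineage
#' @param r_s synonymous substitutions per synonymous site per myr
#' @param f_functional acceptance probability of nonsynonymous changes in
#'   functional lineages (0..1)
#' @param n_codons codons per simulated gene
#' @param kappa transition/transversion ratio of candidate mutations
#'   (default 1 = no bias, which keeps NG86 unbiased)
#' @param n_root_genes gene lineages present at the root
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, gain_rate = 0.7, loss_rate = 0.6,
                       pseudo_rate = 0.19, r_s = 0.002,
                       f_functional = 0.24, n_codons = 500, kappa = 1,
                       n_root_genes = 22) {
  stopifnot(gain_rate >= 0, loss_rate >= 0, pseudo_rate >= 0, r_s >= 0,
            f_functional >= 0, f_functional <= 1, n_codons >= 1, kappa > 0,
            n_root_genes >= 1)
  structure(list(seed = as.integer(seed), gain_rate = gain_rate,
                 loss_rate = loss_rate, pseudo_rate = pseudo_rate,
                 r_s = r_s, f_functional = f_functional,
                 n_codons = as.integer(n_codons), kappa = kappa,
                 n_root_genes = as.integer(n_root_genes)),
            class = "sim_config")
}

# counter-based stream seeds: independent stages use distinct stream ids
stream_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 65011) * 33029 + 7919 * stream) %% 2147483646L + 1L
}

#' Simulate gene content evolution on a chronogram
#'
#' Each root gene lineage evolves independently along the tree; on every
#' branch, gains (duplications within the lineage's ortholog group),
#' losses and pseudogenizations arrive as Poisson processes at the
#' configured per-100-myr rates. Gains add a functional copy to the same
#' group; losses remove a copy; pseudogenization relabels a copy, which
#' then stays inert. The returned matrix tallies functional copies per
#' group and species.
#'
#' @param tree a chronogram
#' @param config a [sim_config()]
#' @return list with `matrix` (groups x species functional counts),
#'   `pseudo_matrix` (pseudogene copies), `truth` (tibble of true events:
#'   group, type, node, branch_label, time_mya)
#' @export
simulate_gene_content <- function(tree, config = sim_config()) {
  tree <- as_chronogram(tree)
  ages <- node_ages(tree)
  root <- ape::Ntip(tree) + 1L
  depth <- ages[root]
  net <- (config$gain_rate - config$loss_rate) / 100
  expected <- config$n_root_genes * exp(max(net, 0) * depth)
  if (expected > 10000)
    stop("explosive settings: expected ", round(expected),
         " lineages (> 10,000); lower gain_rate or n_root_genes",
         call. = FALSE)
  set.seed(stream_seed(config$seed, 1L))
  n <- ape::Ntip(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  node_label <- function(v) if (v <= n) tree$tip.label[v] else paste0("node", v)
  rates <- c(gain = config$gain_rate, loss = config$loss_rate,
             pseudogenization = config$pseudo_rate) / 100
  total_rate <- sum(rates)
  events <- list()
  groups <- paste0("g", seq_len(config$n_root_genes))
  leaf_counts <- matrix(0L, config$n_root_genes, n,
                        dimnames = list(groups, tree$tip.label))
  leaf_pseudo <- leaf_counts
  n_live <- config$n_root_genes
  next_id <- config$n_root_genes + 1L
  # copies: data.frame(id, group, status, t_start); t_start is the copy's
  # birth offset within the current branch (0 for copies inherited from
  # the parent node), so mid-branch duplicates only evolve the remainder
  walk <- function(node, copies) {
    if (node != root) {
      parent <- tree$edge[tree$edge[, 2] == node, 1]
      dur <- ages[parent] - ages[node]
      if (dur > 0 && nrow(copies) > 0 && total_rate > 0) {
        i <- 1L
        while (i <= nrow(copies)) {
          if (copies$status[i] == "functional") {
            t <- copies$t_start[i]
            repeat {
              t <- t + stats::rexp(1, total_rate)
              if (t > dur) break
              type <- sample(names(rates), 1, prob = rates)
              events[[length(events) + 1L]] <<- list(
                group = copies$group[i], lineage = copies$id[i],
                type = type, node = as.integer(node),
                branch_label = node_label(node),
                time_mya = ages[parent] - t)
              if (type == "gain") {
                n_live <<- n_live + 1L
                if (n_live > 10000)
                  stop("explosive settings: > 10,000 live lineages",
                       call. = FALSE)
                copies <- rbind(copies,
                                data.frame(id = next_id,
                                           group = copies$group[i],
                                           status = "functional",
                                           t_start = t))
                next_id <<- next_id + 1L
              } else if (type == "loss") {
                copies <- copies[-i, , drop = FALSE]
                i <- i - 1L
                break
              } else {
                copies$status[i] <- "pseudogene"
                break
              }
            }
          }
          i <- i + 1L
        }
      }
    }
    if (node <= n) {
      for (g in unique(copies$group)) {
        leaf_counts[g, node] <<- sum(copies$group == g &
                                       copies$status == "functional")
        leaf_pseudo[g, node] <<- sum(copies$group == g &
                                       copies$status == "pseudogene")
      }
    } else {
      if (nrow(copies) > 0) copies$t_start <- 0
      for (ch in children[[as.character(node)]]) walk(ch, copies)
    }
  }
  walk(root, data.frame(id = seq_len(config$n_root_genes), group = groups,
                        status = "functional", t_start = 0))
  truth <- if (length(events)) dplyr::bind_rows(lapply(events, tibble::as_tibble)) else
    tibble::tibble(group = character(), lineage = integer(),
                   type = character(), node = integer(),
                   branch_label = character(), time_mya = numeric())
  list(matrix = leaf_counts, pseudo_matrix = leaf_pseudo, truth = truth)
}

# --- codon sequence evolution ------------------------------------------

#' Draw a random root coding sequence
#' @param n_codons length in codons
#' @return integer codon vector (uniform over the 61 sense codons)
#' @keywords internal
random_root_codons <- function(n_codons) {
  sense <- which(!codon_is_stop())
  sense[sample.int(length(sense), n_codons, replace = TRUE)]
}

# Evolve an integer codon sequence for `duration` myr. Candidate
# single-nucleotide changes arrive at rate r_s/3 per codon per change slot
# (9 slots), so the synonymous substitution rate per synonymous site is
# exactly r_s. Synonymous candidates are always accepted, nonsynonymous
# with probability f; candidates creating stop codons are rejected in
# functional regimes and accepted in pseudogene regimes.
evolve_codons <- function(seq, duration, f, pseudo, r_s, kappa = 1) {
  L <- length(seq)
  if (duration <= 0 || r_s <= 0) return(seq)
  nb <- codon_neighbors()
  aa <- codon_aa()
  stop_flag <- codon_is_stop()
  n_cand <- stats::rpois(1, 3 * r_s * L * duration)
  if (n_cand == 0) return(seq)
  pos <- sample.int(L, n_cand, replace = TRUE)
  u <- stats::runif(n_cand)
  if (kappa == 1) {
    slot <- sample.int(9L, n_cand, replace = TRUE)
  } else {
    ts <- codon_transitions()
    slot <- integer(n_cand)
    for (i in seq_len(n_cand)) {
      w <- ifelse(ts[seq[pos[i]], ], kappa, 1)
      slot[i] <- sample.int(9L, 1L, prob = w)
    }
  }
  for (i in seq_len(n_cand)) {
    cur <- seq[pos[i]]
    tgt <- nb[cur, slot[i]]
    if (stop_flag[tgt] && !pseudo) next
    if (aa[cur] == aa[tgt] || u[i] < f) seq[pos[i]] <- tgt
  }
  seq
}

#' Simulate codon sequences along a gene tree
#'
#' Gillespie-style codon evolution: a clock-like synonymous rate, an
#' acceptance probability `f` for nonsynonymous changes, and optional
#' per-branch regime switches to neutral pseudogene evolution (f = 1,
#' stop codons allowed) at a given time offset from the start (rootward
#' end) of a branch; the switched regime is inherited by all descendants.
#'
#' @param tree ape `phylo` with branch lengths in myr (durations)
#' @param config a [sim_config()]
#' @param regimes optional tibble with columns `node` (branch identified by
#'   its child node number or tip label), `offset` (myr from the start of
#'   that branch) and `f` (new acceptance probability; `1` = pseudogene)
#' @param root_seq optional integer codon vector to start from
#' @return list with `alignment` (codon `cyp_alignment` of the tips),
#'   `truth` (tibble: node, branch_label, f_start, f_end, switched)
#' @export
simulate_codon_sequences <- function(tree, config = sim_config(),
                                     regimes = NULL, root_seq = NULL) {
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch durations", call. = FALSE)
  set.seed(stream_seed(config$seed, 2L))
  if (is.null(root_seq)) root_seq <- random_root_codons(config$n_codons)
  n <- ape::Ntip(tree)
  root <- n + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  node_label <- function(v) if (v <= n) tree$tip.label[v] else paste0("node", v)
  if (!is.null(regimes)) {
    regimes <- tibble::as_tibble(regimes)
    if (is.character(regimes$node))
      regimes$node <- match(regimes$node, tree$tip.label)
    if (!"pseudo" %in% names(regimes)) regimes$pseudo <- regimes$f >= 1
  }
  seqs <- vector("list", n)
  t_node <- integer(0); t_lab <- character(0)
  t_f0 <- numeric(0); t_f1 <- numeric(0)
  walk <- function(node, seq, f, pseudo) {
    if (node != root) {
      e <- which(tree$edge[, 2] == node)
      dur <- tree$edge.length[e]
      f0 <- f
      sw <- if (is.null(regimes)) NULL else regimes[regimes$node == node, ]
      if (!is.null(sw) && nrow(sw) == 1L && sw$offset <= dur) {
        seq <- evolve_codons(seq, sw$offset, f, pseudo, config$r_s,
                             config$kappa)
        f <- sw$f
        pseudo <- sw$pseudo
        seq <- evolve_codons(seq, dur - sw$offset, f, pseudo, config$r_s,
                             config$kappa)
      } else {
        seq <- evolve_codons(seq, dur, f, pseudo, config$r_s, config$kappa)
      }
      t_node <<- c(t_node, as.integer(node))
      t_lab <<- c(t_lab, node_label(node))
      t_f0 <<- c(t_f0, f0); t_f1 <<- c(t_f1, f)
    }
    if (node <= n) {
      seqs[[node]] <<- seq
    } else {
      for (ch in children[[as.character(node)]]) walk(ch, seq, f, pseudo)
    }
  }
  walk(root, root_seq, config$f_functional, FALSE)
  strings <- vapply(seqs, function(s) paste(int_to_codon(s), collapse = ""),
                    character(1))
  names(strings) <- tree$tip.label
  list(alignment = new_alignment(strings, "codon"),
       truth = tibble::tibble(node = t_node, branch_label = t_lab,
                              f_start = t_f0, f_end = t_f1,
                              switched = t_f1 != t_f0))
}

#' Simulate a duplication scenario for clock dating
#'
#' Builds a gene tree with a duplication at `t_dup` mya and, within each of
#' the two duplicate clades, a species calibration split at `t_cal` mya
#' separating two tips (an `X` species and a `Z` species per clade), then
#' simulates clock-like codon sequences on it.
#'
#' @param t_dup duplication age, mya (must exceed `t_cal`)
#' @param t_cal calibration split age, mya
#' @param config a [sim_config()]
#' @return list with `tree` (durations in myr), `alignment`, `truth`
#'   (including the expected `b_pre`/`b_post` ratio `(t_dup - t_cal) /
#'   t_cal` under the clock)
#' @export
simulate_duplication_scenario <- function(t_dup, t_cal,
                                          config = sim_config()) {
  if (t_dup <= t_cal) stop("t_dup must exceed t_cal", call. = FALSE)
  d <- t_dup - t_cal
  nwk <- sprintf("((A_X:%f,A_Z:%f):%f,(B_X:%f,B_Z:%f):%f);",
                 t_cal, t_cal, d, t_cal, t_cal, d)
  tree <- ape::read.tree(text = nwk)
  sim <- simulate_codon_sequences(tree, config)
  list(tree = tree, alignment = sim$alignment,
       truth = list(t_dup = t_dup, t_cal = t_cal,
                    expected_ratio = d / t_cal,
                    branches = sim$truth))
}
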