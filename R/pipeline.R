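# File-based orchestration of the analysis stages. Stages communicate only
# through files in the run directory, so any stage can be replaced by a
# fixture; every run records its seed and configuration.

#' Build a pipeline run configuration
#'
#' @param outdir run directory (created if absent)
#' @param seed master seed, recorded in all outputs
#' @param ... further settings; recognised keys include `n_codons`, `r_s`,
#'   `f_functional`, `gain_rate`, `loss_rate`, `pseudo_rate`,
#'   `n_root_genes`, `max_gap_fraction`, `deletion`, `bootstrap_reps`,
#'   `min_support`, `tree_file` (chronogram for simulation/events),
#'   `reference_types` (named list for classify), `window_myr`,
#'   `calibration` (list with `side_a`, `side_b`, `t_cal`),
#'   `pseudogene_pairs` (data frame: pseudo, functional, T_div, f)
#' @return a `run_config` list
#' @export
run_config <- function(outdir, seed = 1, ...) {
  cfg <- c(list(outdir = outdir, seed = as.integer(seed)), list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Read/write a run configuration as JSON
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_run_config
#' @param config a `run_config`
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

stage_path <- function(config, file) file.path(config$outdir, file)

require_input <- function(config, file, producer) {
  p <- stage_path(config, file)
  if (!file.exists(p))
    stop("missing input '", file, "': run stage '", producer, "' first",
         call. = FALSE)
  p
}

log_line <- function(config, ...) {
  cat(paste0(..., "\n"), file = stage_path(config, "run.log"), append = TRUE)
}

cfg_policy <- function(config) {
  site_filter_policy(config$max_gap_fraction %||% 0.20,
                     config$deletion %||% "pairwise")
}

cfg_simconfig <- function(config) {
  sim_config(seed = config$seed,
             gain_rate = config$gain_rate %||% 0.7,
             loss_rate = config$loss_rate %||% 0.6,
             pseudo_rate = config$pseudo_rate %||% 0.19,
             r_s = config$r_s %||% 0.002,
             f_functional = config$f_functional %||% 0.24,
             n_codons = config$n_codons %||% 500,
             kappa = config$kappa %||% 1,
             n_root_genes = config$n_root_genes %||% 22)
}

cfg_tree <- function(config) {
  if (!is.null(config$tree_file)) read_newick(config$tree_file,
                                              chronogram = TRUE)
  else cyp_vertebrate_chronogram()
}

#' Run one pipeline stage
#'
#' Stages: `"simulate"` (gene content + codon alignment from the seeded
#' generators), `"distances"`, `"tree"` (NJ, optional bootstrap),
#' `"classify"` (B/D assignment), `"events"` (Dollo reconstruction +
#' rates), `"date-duplication"`, `"date-pseudogene"`, `"constraint"`,
#' `"report"` (aggregates stage outputs into `report.tsv`). A missing
#' upstream output raises an error naming the producing stage.
#'
#' @param stage stage name
#' @param config a [run_config()]
#' @return invisible list of written paths
#' @export
run_stage <- function(stage, config) {
  stage <- match.arg(stage, c("simulate", "distances", "tree", "classify",
                              "events", "date-duplication",
                              "date-pseudogene", "constraint", "report"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, stage_path(config, "config.json"))
  log_line(config, "[", stage, "] seed=", config$seed)
  out <- switch(stage,
    simulate = stage_simulate(config),
    distances = stage_distances(config),
    tree = stage_tree(config),
    classify = stage_classify(config),
    events = stage_events(config),
    `date-duplication` = stage_date_duplication(config),
    `date-pseudogene` = stage_date_pseudogene(config),
    constraint = stage_constraint(config),
    report = stage_report(config))
  invisible(out)
}

stage_simulate <- function(config) {
  sc <- cfg_simconfig(config)
  tree <- cfg_tree(config)
  gc <- simulate_gene_content(tree, sc)
  write_presence_absence(gc$matrix, stage_path(config, "gene_content.tsv"))
  readr::write_tsv(gc$truth, stage_path(config, "truth_events.tsv"))
  sim <- simulate_codon_sequences(tree, sc)
  write_alignment(sim$alignment, stage_path(config, "alignment.fasta"))
  readr::write_tsv(sim$truth, stage_path(config, "truth_regimes.tsv"))
  list(gene_content = stage_path(config, "gene_content.tsv"),
       alignment = stage_path(config, "alignment.fasta"))
}

stage_distances <- function(config) {
  aln <- read_alignment(require_input(config, "alignment.fasta", "simulate"),
                        type = "codon")
  pol <- cfg_policy(config)
  D <- distance_matrix(aln, "p", pol,
                       correction = config$correction %||% "none")
  write_distance_matrix(D, stage_path(config, "distances_p.tsv"))
  list(distances = stage_path(config, "distances_p.tsv"))
}

stage_tree <- function(config) {
  reps <- config$bootstrap_reps %||% 0
  if (reps > 0) {
    aln <- read_alignment(require_input(config, "alignment.fasta",
                                        "simulate"), type = "codon")
    pol <- cfg_policy(config)
    tr <- bootstrap_support(aln, function(a) distance_matrix(a, "p", pol),
                            n_reps = reps, seed = config$seed)
  } else {
    D <- read_distance_matrix(require_input(config, "distances_p.tsv",
                                            "distances"))
    tr <- nj_build(D)
  }
  write_newick(tr, stage_path(config, "tree.nwk"))
  list(tree = stage_path(config, "tree.nwk"))
}

stage_classify <- function(config) {
  tr <- read_newick(require_input(config, "tree.nwk", "tree"))
  refs <- unlist(config$reference_types)
  if (is.null(refs)) stop("config$reference_types required for classify",
                          call. = FALSE)
  rooted <- if (ape::is.rooted(tr)) tr else
    root_with_outgroup(tr, names(refs)[1])
  res <- assign_type(rooted, refs, min_support = config$min_support %||% 80)
  readr::write_tsv(res, stage_path(config, "assignments.tsv"))
  list(assignments = stage_path(config, "assignments.tsv"))
}

stage_events <- function(config) {
  m <- read_presence_absence(require_input(config, "gene_content.tsv",
                                           "simulate"))
  tree <- cfg_tree(config)
  rec <- dollo_reconstruct(m, tree)
  write_events(rec$events, stage_path(config, "events.tsv"))
  readr::write_tsv(tibble::as_tibble(rec$ancestral_counts,
                                     rownames = "node"),
                   stage_path(config, "ancestral_counts.tsv"))
  window <- config$window_myr %||% total_branch_length(tree)
  rates <- tibble::tibble(
    type = c("gain", "loss", "pseudogenization"),
    count = c(count_events(rec$events, "gain"),
              count_events(rec$events, "loss"),
              count_events(rec$events, "pseudogenization")),
    window_myr = window)
  rates$rate_per_100myr <- event_rate(rates$count, rates$window_myr)
  readr::write_tsv(rates, stage_path(config, "rates.tsv"))
  list(events = stage_path(config, "events.tsv"),
       rates = stage_path(config, "rates.tsv"))
}

stage_date_duplication <- function(config) {
  cal <- config$calibration
  if (is.null(cal)) stop("config$calibration required", call. = FALSE)
  aln <- read_alignment(require_input(config, "alignment.fasta", "simulate"),
                        type = "codon")
  tr <- read_newick(require_input(config, "tree.nwk", "tree"))
  res <- duplication_time_from_alignment(aln, tr,
                                         unlist(cal$side_a),
                                         unlist(cal$side_b),
                                         cal$t_cal, policy = cfg_policy(config))
  readr::write_tsv(res$estimates, stage_path(config, "duplication_dates.tsv"))
  list(dates = stage_path(config, "duplication_dates.tsv"))
}

stage_date_pseudogene <- function(config) {
  pairs <- config$pseudogene_pairs
  if (is.null(pairs)) stop("config$pseudogene_pairs required", call. = FALSE)
  pairs <- tibble::as_tibble(pairs)
  aln <- read_alignment(require_input(config, "alignment.fasta", "simulate"),
                        type = "codon")
  pol <- cfg_policy(config)
  res <- purrr::pmap_dfr(pairs, function(pseudo, functional, T_div, f, ...) {
    R <- pair_ratio(unclass(aln)[pseudo, ], unclass(aln)[functional, ], pol)
    dplyr::mutate(pseudogenization_time(R, f, T_div),
                  pseudo = pseudo, functional = functional)
  })
  readr::write_tsv(res, stage_path(config, "pseudogene_dates.tsv"))
  list(dates = stage_path(config, "pseudogene_dates.tsv"))
}

stage_constraint <- function(config) {
  genes <- config$constraint_genes
  if (is.null(genes))
    stop("config$constraint_genes (list of gene -> alignment file) required",
         call. = FALSE)
  topo <- read_newick(require_input(config, "species_topology.nwk",
                                    "user-supplied species_topology.nwk"))
  pol <- cfg_policy(config)
  res <- purrr::imap_dfr(genes, function(path, gene) {
    aln <- read_alignment(path, type = "codon")
    dplyr::select(estimate_f(aln, topo, pol, gene = gene),
                  "gene", "f", "constraint", "sum_bN", "sum_bS", "n_clamped")
  })
  readr::write_tsv(res, stage_path(config, "constraint.tsv"))
  list(constraint = stage_path(config, "constraint.tsv"))
}

stage_report <- function(config) {
  inputs <- c(rates = "rates.tsv", constraint = "constraint.tsv",
              assignments = "assignments.tsv",
              duplication = "duplication_dates.tsv",
              pseudogene = "pseudogene_dates.tsv")
  present <- file.exists(vapply(inputs, function(f) stage_path(config, f),
                                character(1)))
  names(present) <- names(inputs)
  if (!any(present))
    stop("report: no stage outputs found; required at least one of: ",
         paste(inputs, collapse = ", "), call. = FALSE)
  rows <- list()
  add <- function(metric, value, source) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      metric = metric, value = value, source = source)
  }
  if (present["rates"]) {
    rates <- readr::read_tsv(stage_path(config, "rates.tsv"),
                             show_col_types = FALSE)
    for (i in seq_len(nrow(rates))) {
      add(paste0(rates$type[i], "_count"), rates$count[i], "rates.tsv")
      add(paste0(rates$type[i], "_rate_per_100myr"),
          signif(rates$rate_per_100myr[i], 2), "rates.tsv")
    }
  }
  if (present["constraint"]) {
    ct <- readr::read_tsv(stage_path(config, "constraint.tsv"),
                          show_col_types = FALSE)
    add("median_f", stats::median(ct$f, na.rm = TRUE), "constraint.tsv")
    add("mean_f", mean(ct$f, na.rm = TRUE), "constraint.tsv")
  }
  if (present["duplication"]) {
    dd <- readr::read_tsv(stage_path(config, "duplication_dates.tsv"),
                          show_col_types = FALSE)
    add("duplication_min_estimate_mya", min(dd$estimate),
        "duplication_dates.tsv")
  }
  if (present["pseudogene"]) {
    pd <- readr::read_tsv(stage_path(config, "pseudogene_dates.tsv"),
                          show_col_types = FALSE)
    add("pseudogenization_mean_t_mya", mean(pd$t), "pseudogene_dates.tsv")
  }
  rep <- dplyr::bind_rows(rows)
  readr::write_tsv(rep, stage_path(config, "report.tsv"))
  list(report = stage_path(config, "report.tsv"))
}
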