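# Codon machinery shared by the NG86 counters and the sequence simulators.
# Codons are handled as integers 1..64 (T,C,A,G nesting, position 3 fastest);
# all per-codon quantities are precomputed once per session and cached.

.cyp_cache <- new.env(parent = emptyenv())

.bases <- c("T", "C", "A", "G")

#' All 64 codons in fixed table order
#' @return character vector of length 64
#' @keywords internal
codon_table_order <- function() {
  if (is.null(.cyp_cache$codons)) {
    g <- expand.grid(p3 = .bases, p2 = .bases, p1 = .bases,
                     stringsAsFactors = FALSE)
    .cyp_cache$codons <- paste0(g$p1, g$p2, g$p3)
  }
  .cyp_cache$codons
}

codon_aa <- function() {
  if (is.null(.cyp_cache$aa)) {
    gc <- Biostrings::GENETIC_CODE
    .cyp_cache$aa <- unname(gc[codon_table_order()])
  }
  .cyp_cache$aa
}

codon_is_stop <- function() codon_aa() == "*"

codon_to_int <- function(x) {
  match(x, codon_table_order())
}

int_to_codon <- function(i) codon_table_order()[i]

# nb[i, k]: codon reached from codon i by candidate change k (k = 3*(pos-1)+j,
# j indexing the three alternative bases at that position).
codon_neighbors <- function() {
  if (is.null(.cyp_cache$nb)) {
    codons <- codon_table_order()
    nb <- matrix(0L, 64L, 9L)
    transition <- matrix(FALSE, 64L, 9L)
    ts_pair <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in seq_len(64L)) {
      cod <- strsplit(codons[i], "")[[1]]
      k <- 0L
      for (pos in 1:3) {
        for (alt in setdiff(.bases, cod[pos])) {
          k <- k + 1L
          mut <- cod
          mut[pos] <- alt
          nb[i, k] <- codon_to_int(paste(mut, collapse = ""))
          transition[i, k] <- identical(unname(ts_pair[cod[pos]]), alt)
        }
      }
    }
    .cyp_cache$nb <- nb
    .cyp_cache$transition <- transition
  }
  .cyp_cache$nb
}

codon_transitions <- function() {
  codon_neighbors()
  .cyp_cache$transition
}

#' Nei-Gojobori synonymous and nonsynonymous site counts for one codon
#'
#' Each codon position contributes the fraction of its counted (non-stop)
#' single-nucleotide changes that are synonymous; mutations creating stop
#' codons are excluded from the denominator, so every position contributes
#' exactly one site and `S + N = 3` per sense codon.
#'
#' @param codon a 3-letter codon string (unambiguous, not a stop codon)
#' @return named numeric vector `c(S = , N = )`
#' @examples
#' ng86_site_counts("TTT") # S = 1/3
#' @export
ng86_site_counts <- function(codon) {
  i <- codon_to_int(toupper(codon))
  if (is.na(i)) stop("not an unambiguous codon: ", codon, call. = FALSE)
  if (codon_is_stop()[i]) stop("stop codon has no NG86 sites: ", codon, call. = FALSE)
  sn <- codon_site_table()
  c(S = sn$S[i], N = sn$N[i])
}

codon_site_table <- function() {
  if (is.null(.cyp_cache$sites)) {
    nb <- codon_neighbors()
    aa <- codon_aa()
    stop_flag <- codon_is_stop()
    S <- N <- rep(NA_real_, 64L)
    for (i in seq_len(64L)) {
      if (stop_flag[i]) next
      s_tot <- 0
      for (pos in 1:3) {
        ks <- (3L * (pos - 1L) + 1L):(3L * pos)
        targets <- nb[i, ks]
        counted <- !stop_flag[targets]
        if (!any(counted)) next    # cannot occur with the standard code
        syn <- sum(aa[targets[counted]] == aa[i])
        s_tot <- s_tot + syn / sum(counted)
      }
      S[i] <- s_tot
      N[i] <- 3 - s_tot
    }
    .cyp_cache$sites <- list(S = S, N = N)
  }
  .cyp_cache$sites
}

# Pathway-averaged synonymous difference count between two sense codons.
# All minimal pathways (orders of the differing positions) are enumerated;
# pathways passing through a stop intermediate are dropped unless every
# pathway does, in which case all are averaged.
codon_pair_diff <- function(i, j) {
  tab <- codon_pair_table()
  c(sd = tab$SD[i, j], nd = tab$ND[i, j])
}

codon_pair_table <- function() {
  if (!is.null(.cyp_cache$pairs)) return(.cyp_cache$pairs)
  codons <- codon_table_order()
  aa <- codon_aa()
  stop_flag <- codon_is_stop()
  split_codons <- strsplit(codons, "")
  SD <- ND <- matrix(0, 64L, 64L)
  perms <- list(
    `1` = matrix(1L, 1, 1),
    `2` = rbind(c(1L, 2L), c(2L, 1L)),
    `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  for (i in seq_len(64L)) {
    if (stop_flag[i]) next
    a <- split_codons[[i]]
    for (j in seq_len(64L)) {
      if (stop_flag[j] || i == j) next
      b <- split_codons[[j]]
      diffpos <- which(a != b)
      k <- length(diffpos)
      pm <- perms[[as.character(k)]]
      syn_counts <- numeric(nrow(pm))
      ok <- logical(nrow(pm))
      for (p in seq_len(nrow(pm))) {
        cur <- a
        syn <- 0
        valid <- TRUE
        for (step in pm[p, ]) {
          nxt <- cur
          nxt[diffpos[step]] <- b[diffpos[step]]
          ci <- codon_to_int(paste(cur, collapse = ""))
          ni <- codon_to_int(paste(nxt, collapse = ""))
          if (stop_flag[ni] && ni != j) valid <- FALSE
          if (aa[ci] == aa[ni]) syn <- syn + 1
          cur <- nxt
        }
        syn_counts[p] <- syn
        ok[p] <- valid
      }
      use <- if (any(ok)) syn_counts[ok] else syn_counts
      SD[i, j] <- mean(use)
      ND[i, j] <- k - mean(use)
    }
  }
  .cyp_cache$pairs <- list(SD = SD, ND = ND)
  .cyp_cache$pairs
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' @param p proportion of differing sites (per site)
#' @return corrected distance; `NA` (saturated) where `p >= 3/4`
#' @export
jukes_cantor <- function(p) {
  d <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
  d[p == 0] <- 0
  d
}
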