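# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (string-based genetic code lookups, explicit
# enumeration) so that agreement is informative.

oracle_code <- as.character(Biostrings::GENETIC_CODE)
names(oracle_code) <- names(Biostrings::GENETIC_CODE)

oracle_translate <- function(codon) unname(oracle_code[codon])

oracle_neighbors <- function(codon) {
  out <- character(0)
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) != b) {
        mut <- codon
        substr(mut, pos, pos) <- b
        out <- c(out, mut)
      }
    }
  }
  out
}

# per-position NG86 site fractions by direct enumeration
oracle_site_counts <- function(codon) {
  s_total <- 0
  for (pos in 1:3) {
    syn <- 0
    counted <- 0
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracle_translate(mut) == "*") next
      counted <- counted + 1
      if (oracle_translate(mut) == oracle_translate(codon)) syn <- syn + 1
    }
    if (counted > 0) s_total <- s_total + syn / counted
  }
  c(S = s_total, N = 3 - s_total)
}

# pathway-averaged (Sd, Nd) by recursive enumeration of substitution orders
oracle_pair_diff <- function(a, b) {
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diffpos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, syn, through_stop) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- list(syn = syn, stop = through_stop)
      return()
    }
    for (r in seq_along(remaining)) {
      pos <- remaining[r]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_syn <- oracle_translate(cur) == oracle_translate(nxt)
      hit_stop <- oracle_translate(nxt) == "*" && nxt != b
      recurse(nxt, remaining[-r], syn + step_syn, through_stop || hit_stop)
    }
  }
  recurse(a, diffpos, 0, FALSE)
  ok <- !vapply(paths, `[[`, logical(1), "stop")
  use <- if (any(ok)) paths[ok] else paths
  sd <- mean(vapply(use, `[[`, numeric(1), "syn"))
  c(sd = sd, nd = k - sd)
}

sense_codons <- function() {
  cods <- names(oracle_code)[oracle_code != "*"]
  cods
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# random ultrametric chronogram over n species (birth times uniform)
random_chronogram <- function(n, depth = 100) {
  tr <- ape::rcoal(n, tip.label = paste0("sp", seq_len(n)))
  tr$edge.length <- tr$edge.length * depth / max(ape::node.depth.edgelength(tr))
  as_chronogram(tr)
}

# OLS SSE objective for the independent optimiser route
ols_sse_fn <- function(topology, D) {
  tr <- ape::unroot(topology)
  tips <- tr$tip.label
  prs <- utils::combn(length(tips), 2)
  d <- unclass(D)[cbind(match(tips[prs[1, ]], rownames(D)),
                        match(tips[prs[2, ]], rownames(D)))]
  paths <- ape::dist.nodes(tr)
  function(beta) {
    tr$edge.length <- beta
    fit <- ape::dist.nodes(tr)[seq_along(tips), seq_along(tips)]
    fitv <- fit[cbind(prs[1, ], prs[2, ])]
    sum((d - fitv)^2)
  }
}

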