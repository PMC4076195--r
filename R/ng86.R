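# Nei-Gojobori (1986) pathway counting of synonymous and nonsynonymous sites
# and differences for a pair of in-frame coding sequences, with optional
# Jukes-Cantor correction of the proportions.

#' Nei-Gojobori synonymous/nonsynonymous counts for a codon sequence pair
#'
#' Site counts `S` and `N` are averaged over the two sequences; differences
#' `Sd` and `Nd` are averaged with equal weight over all minimal substitution
#' pathways for codons differing at 2-3 positions, preferring pathways that
#' avoid stop-codon intermediates. Codons containing missing data in either
#' sequence are excluded (pairwise deletion); codon pairs in which either
#' codon is a stop are skipped with a warning. Proportions are corrected with
#' the Jukes-Cantor formula `d = -3/4 log(1 - 4p/3)` unless
#' `correction = "none"`.
#'
#' @param a,b aligned in-frame nucleotide sequences (strings or character
#'   vectors), equal length divisible by 3
#' @param policy a [site_filter_policy()] (deletion mode; gap-rich-column
#'   exclusion is applied upstream by [filter_columns()])
#' @param correction `"jukes_cantor"` (default) or `"none"`
#' @return one-row tibble with columns `codons` (compared codons), `S`, `N`,
#'   `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`, `saturated`
#' @examples
#' ng86_pair("TTTGGG", "TTCGGA")
#' @export
ng86_pair <- function(a, b, policy = site_filter_policy(),
                      correction = c("jukes_cantor", "none")) {
  correction <- match.arg(correction)
  ab <- as_char_pair(a, b)
  if (length(ab$a) %% 3L != 0L)
    stop("frame error: sequence length not divisible by 3", call. = FALSE)
  res <- ng86_pair_int(row_to_codons(ab$a), row_to_codons(ab$b), correction)
  tibble::as_tibble(res)
}

# fast path on integer codon vectors (NA = missing); returns a plain list
ng86_pair_int <- function(ca, cb, correction = "jukes_cantor") {
  keep <- !is.na(ca) & !is.na(cb)
  stop_flag <- codon_is_stop()
  is_stop_pair <- keep
  is_stop_pair[keep] <- stop_flag[ca[keep]] | stop_flag[cb[keep]]
  if (any(is_stop_pair)) {
    warning(sum(is_stop_pair), " codon pair(s) containing a stop codon skipped")
    keep <- keep & !is_stop_pair
  }
  ca <- ca[keep]; cb <- cb[keep]
  n_codons <- length(ca)
  sites <- codon_site_table()
  S <- (sum(sites$S[ca]) + sum(sites$S[cb])) / 2
  N <- (sum(sites$N[ca]) + sum(sites$N[cb])) / 2
  tab <- codon_pair_table()
  Sd <- sum(tab$SD[cbind(ca, cb)])
  Nd <- sum(tab$ND[cbind(ca, cb)])
  pS <- if (isTRUE(S > 0)) Sd / S else NA_real_
  pN <- if (isTRUE(N > 0)) Nd / N else NA_real_
  if (correction == "jukes_cantor") {
    dS <- jukes_cantor(pS)
    dN <- jukes_cantor(pN)
  } else {
    dS <- pS
    dN <- pN
  }
  saturated <- (isTRUE(pS >= 0.75)) || (isTRUE(pN >= 0.75))
  list(codons = n_codons, S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, dS = dS, dN = dN, saturated = saturated)
}
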