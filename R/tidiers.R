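# broom-style tidiers and re-exports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Mann-Whitney comparison
#' @param x a `cyp_mwu`
#' @param ... unused
#' @return one-row tibble with `U`, `p_value`, `method`, `n1`, `n2`
#' @exportS3Method generics::tidy
tidy.cyp_mwu <- function(x, ...) {
  tibble::tibble(U = x$U, p_value = x$p_value, method = x$method,
                 n1 = x$n1, n2 = x$n2)
}

#' @rdname tidy.cyp_mwu
#' @exportS3Method generics::glance
glance.cyp_mwu <- function(x, ...) tidy.cyp_mwu(x)

#' Tidy a B-vs-D constraint comparison
#' @param x a `cyp_type_comparison`
#' @param ... unused
#' @return per-type summary tibble with the test appended as columns
#' @exportS3Method generics::tidy
tidy.cyp_type_comparison <- function(x, ...) x$summary

#' @rdname tidy.cyp_type_comparison
#' @exportS3Method generics::glance
glance.cyp_type_comparison <- function(x, ...) {
  dplyr::mutate(tidy.cyp_mwu(x$test),
                median_B = x$summary$median[x$summary$cyp_type == "B"],
                median_D = x$summary$median[x$summary$cyp_type == "D"])
}

#' Tidy a duplication-dating result
#' @param x a `cyp_duplication_dating`
#' @param ... unused
#' @return per-lineage estimate tibble
#' @exportS3Method generics::tidy
tidy.cyp_duplication_dating <- function(x, ...) x$estimates

#' @rdname tidy.cyp_duplication_dating
#' @exportS3Method generics::glance
glance.cyp_duplication_dating <- function(x, ...) {
  tibble::tibble(minimum = x$minimum, low = x$range[1], high = x$range[2],
                 n_lineages = nrow(x$estimates), t_cal = x$t_cal)
}

#' Tidy a distance matrix to long format
#' @param x a `cyp_dist`
#' @param ... unused
#' @return tibble with `item1`, `item2`, `distance` (lower triangle)
#' @exportS3Method generics::tidy
tidy.cyp_dist <- function(x, ...) {
  m <- unclass(x)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  tibble::tibble(item1 = rownames(m)[idx[, 1]],
                 item2 = colnames(m)[idx[, 2]],
                 distance = m[idx])
}

#' Tidy a Dollo reconstruction
#' @param x a `cyp_dollo`
#' @param ... unused
#' @return the unit-event tibble
#' @exportS3Method generics::tidy
tidy.cyp_dollo <- function(x, ...) tibble::as_tibble(x$events)

#' @rdname tidy.cyp_dollo
#' @exportS3Method generics::glance
glance.cyp_dollo <- function(x, ...) {
  ev <- x$events
  tibble::tibble(n_events = nrow(ev),
                 n_gains = sum(ev$type == "gain"),
                 n_losses = sum(ev$type == "loss"),
                 n_pseudogenizations = sum(ev$type == "pseudogenization"))
}
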