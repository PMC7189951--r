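#' Parity distribution and primary infertility rate
#'
#' Counts and percentages of women having had at least `k` children,
#' `k = 1..max_children`, with all women as the percentage base, plus the
#' primary infertility rate (percentage of women with no live birth).
#' Percentages are rounded half-up to two decimals.
#'
#' @param x A nonempty `cohort`.
#' @param max_children Largest `k` reported (default 4).
#' @return Object of class `parity_distribution`: `n_women`, and a data
#'   frame `table` with columns `children`, `n`, `pct`, plus
#'   `infertility_rate`.
#' @examples
#' pd <- parity_distribution(make_fixture("tiny8"))
#' pd$infertility_rate
#' @export
parity_distribution <- function(x, max_children = 4L) {
  validate_cohort(x)
  if (!nrow(x)) stop_input("empty cohort")
  p <- parity(x)
  k <- seq_len(max_children)
  n_ge <- vapply(k, function(j) sum(p >= j), integer(1))
  structure(list(
    n_women = nrow(x),
    table = data.frame(children = k, n = n_ge,
                       pct = round_half_up(100 * n_ge / nrow(x), 2)),
    infertility_rate = round_half_up(100 * sum(p == 0) / nrow(x), 2)
  ), class = "parity_distribution")
}

#' @export
print.parity_distribution <- function(x, ...) {
  cat(sprintf("Of %d women:\n", x$n_women))
  for (i in seq_len(nrow(x$table)))
    cat(sprintf("  >= %d child(ren): %d (%.2f%%)\n", x$table$children[i],
                x$table$n[i], x$table$pct[i]))
  cat(sprintf("  primary infertility rate: %.2f%%\n", x$infertility_rate))
  invisible(x)
}

#' Median birth interval
#'
#' Median of the observed (closed) gap times in one or more birth-order
#' strata, in years. Only women who reached the birth contribute; the median
#' of an even count is the mean of the central pair. Stratum 1 is marriage
#' to first birth, stratum `s > 1` the interval before the `s`-th birth.
#'
#' @param x A `cohort`.
#' @param strata Integer vector of birth orders (default `2:4`).
#' @return Named numeric vector of medians in years.
#' @examples
#' median_birth_interval(make_fixture("tiny8"), strata = 1:2)
#' @export
median_birth_interval <- function(x, strata = 2:4) {
  validate_cohort(x)
  p <- parity(x)
  out <- vapply(as.integer(strata), function(s) {
    if (s < 1L) stop_input("strata must be >= 1")
    gaps <- vapply(which(p >= s), function(w) {
      bt <- x$birth_times[[w]]
      bt[s] - if (s == 1L) 0 else bt[s - 1L]
    }, numeric(1))
    if (!length(gaps)) stop_input("no observed births in stratum %d", s)
    median(gaps) / 12
  }, numeric(1))
  setNames(out, sprintf("stratum_%d", strata))
}

#' Sex ratio at a given birth order
#'
#' 100 times the number of male births per female birth among `k`-th
#' births, rounded half-up to an integer. Undefined (NA with a warning)
#' when no female `k`-th birth is recorded.
#'
#' @param x A `cohort`.
#' @param birth_order Birth order `k` (default 1).
#' @return The rounded sex ratio, or `NA` if undefined.
#' @export
sex_ratio <- function(x, birth_order = 1L) {
  validate_cohort(x)
  k <- as.integer(birth_order)
  p <- parity(x)
  sexes <- vapply(which(p >= k), function(w) x$child_sexes[[w]][k],
                  character(1))
  if (!length(sexes)) stop_input("no births of order %d", k)
  males <- sum(sexes == "male")
  females <- sum(sexes == "female")
  if (females == 0) {
    warning("no female births at this order; sex ratio undefined",
            call. = FALSE)
    return(NA_real_)
  }
  round_half_up(100 * males / females, 0)
}

#' Delivery-wise frequency table for one covariate
#'
#' The classic survey reporting table: for each delivery number `s`, the
#' count and percentage of women in each level of a categorical covariate
#' among women with at least `s` births (the delivery's denominator).
#' Percentages are rounded half-up to two decimals.
#'
#' @param x A `cohort`.
#' @param covariate Name of a categorical covariate column.
#' @param max_delivery Highest delivery reported (default 4).
#' @return Data frame of class `frequency_table` with columns `covariate`,
#'   `level`, `delivery`, `denominator`, `n`, `pct`.
#' @examples
#' frequency_table(make_fixture("tiny8"), "woman_employment", 2)
#' @export
frequency_table <- function(x, covariate, max_delivery = 4L) {
  validate_cohort(x)
  if (!covariate %in% names(.factor_levels))
    stop_input("unknown categorical covariate: %s", covariate)
  p <- parity(x)
  rows <- list()
  for (s in seq_len(max_delivery)) {
    in_s <- p >= s
    denom <- sum(in_s)
    counts <- table(x[[covariate]][in_s])
    rows[[s]] <- data.frame(
      covariate = covariate, level = names(counts), delivery = s,
      denominator = denom, n = as.integer(counts),
      pct = if (denom) round_half_up(100 * as.integer(counts) / denom, 2)
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}
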