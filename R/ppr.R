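#' Truncated mean of closed birth intervals
#'
#' Restricted mean occupancy time `E_C(T*) = int_0^C [1 - F(t)] dt` under the
#' empirical distribution of the supplied closed intervals, which reduces to
#' the closed form `mean(pmin(x, C))`. It is nondecreasing in `C` and bounded
#' by both `C` and `mean(x)`.
#'
#' @param x Numeric vector of closed intervals in months (nonempty).
#' @param C Truncation point in months (> 0).
#' @return The truncated mean, in months.
#' @examples
#' trunc_mean_interval(c(24, 48, 96), 60)  # (24 + 48 + 60) / 3 = 44
#' @export
trunc_mean_interval <- function(x, C) {
  if (!length(x)) stop_input("no closed intervals to average")
  if (!is.finite(C) || C <= 0) stop_input("C must be positive")
  if (any(!is.finite(x) | x < 0)) stop_input("intervals must be >= 0")
  mean(pmin(x, C))
}

#' Open and closed birth intervals for one parity transition
#'
#' Extracts from a cohort the ingredients of the parity-progression-ratio
#' estimator for the transition from parity `i` to `i + 1` (with `i = 0`
#' meaning marriage to first birth): the closed intervals
#' `t_{i+1} - t_i` of women who progressed, the open intervals
#' `interview_time - t_i` of women still at parity `i`, and the proportion
#' `p_i(0, C1)` of open intervals at most `C1` months.
#'
#' The denominator of `p_i(0, C1)` is controlled by `open_denominator`. The
#' default `"within_C"` counts only women at parity `i` whose open interval
#' is at most `C`: under a survey that samples women across all marriage
#' durations, those women form a cross-section of the parity-`i` occupancy
#' window on which the renewal identity
#' `p = C1 / (a E_C + (1 - a) C)` holds, making the estimator consistent.
#' `"all"` uses every woman currently at parity `i`; with long-married
#' respondents it drives `p` towards zero and the estimator degenerates, so
#' it is provided for comparison only.
#'
#' @param x A `cohort`.
#' @param transition Parity transition `i >= 0`.
#' @param C1 Short truncation in months (default 12).
#' @param C Long truncation in months (`C > C1`).
#' @param open_denominator `"within_C"` (default) or `"all"`.
#' @return A list of class `interval_data`: `closed`, `open`, `p`,
#'   `n_parity_i`, `n_denominator`, plus the arguments. `p` is `NA` when the
#'   denominator is empty.
#' @export
interval_data <- function(x, transition, C1 = 12, C = 120,
                          open_denominator = c("within_C", "all")) {
  validate_cohort(x)
  open_denominator <- match.arg(open_denominator)
  i <- as.integer(transition)
  if (is.na(i) || i < 0) stop_input("transition must be >= 0")
  if (!is.finite(C1) || !is.finite(C) || C1 <= 0 || C1 >= C)
    stop_input("need 0 < C1 < C")

  p_vec <- parity(x)
  entry <- function(w) if (i == 0) 0 else x$birth_times[[w]][i]
  closed <- vapply(which(p_vec >= i + 1L),
                   function(w) x$birth_times[[w]][i + 1L] - entry(w),
                   numeric(1))
  at_i <- which(p_vec == i)
  open <- vapply(at_i, function(w) x$interview_time[w] - entry(w), numeric(1))
  denom <- if (open_denominator == "within_C") open[open <= C] else open
  p <- if (length(denom)) mean(denom <= C1) else NA_real_

  structure(list(closed = closed, open = open, p = p,
                 n_parity_i = length(open), n_denominator = length(denom),
                 transition = i, C1 = C1, C = C,
                 open_denominator = open_denominator),
            class = "interval_data")
}

#' @export
print.interval_data <- function(x, ...) {
  cat(sprintf("<interval_data> transition %d -> %d (C1=%g, C=%g months)\n",
              x$transition, x$transition + 1L, x$C1, x$C))
  cat(sprintf("  %d closed intervals, %d women at parity %d (%d in denominator)\n",
              length(x$closed), x$n_parity_i, x$transition, x$n_denominator))
  cat(sprintf("  p(0, C1) = %s\n", format(x$p, digits = 4)))
  invisible(x)
}

#' Parity progression ratio from one (p, E_C) pair
#'
#' Point estimate of the parity progression ratio by the open/closed birth
#' interval truncation method,
#' `a = (C1 - p C) / (p (E_C - C))`,
#' where `p` is the proportion of parity-`i` open intervals at most `C1` and
#' `E_C` the truncated mean closed interval. The formula inverts the renewal
#' identity `p = C1 / (a E_C + (1 - a) C)`: the expected time a woman
#' entering parity `i` spends there within a window of `C` months is
#' `a E_C + (1 - a) C`, of which the first `C1` months are occupied by
#' (essentially) everyone. It returns exactly 0 when `p = C1 / C` (no one
#' progresses within the window) and exactly 1 when `p = C1 / E_C` (everyone
#' progresses); values at those analytic limits are snapped to them within a
#' relative tolerance of 1e-9 to absorb floating-point rounding of the
#' inputs. Sampling noise can push the raw value outside `[0, 1]`; the
#' returned `estimate` is clamped and flagged, the raw value kept alongside.
#'
#' @param p Proportion in `(0, 1]`.
#' @param E_c Truncated mean closed interval, months, in `(0, C]`.
#' @param C1,C Truncation points, months, `0 < C1 < C`.
#' @return List with `raw`, `estimate` (clamped to `[0, 1]`) and `in_range`
#'   (`TRUE` when the raw value was already in `[0, 1]`). All `NA` when the
#'   estimate is undefined (`p` zero or missing, or `E_c = C` with a
#'   non-vanishing numerator).
#' @examples
#' ppr_point(p = 0.25, E_c = 36, C1 = 12, C = 60)$estimate  # 0.5
#' @export
ppr_point <- function(p, E_c, C1 = 12, C) {
  if (!is.finite(C1) || !is.finite(C) || C1 <= 0 || C1 >= C)
    stop_input("need 0 < C1 < C")
  undefined <- list(raw = NA_real_, estimate = NA_real_, in_range = NA)
  if (is.na(p) || p == 0) return(undefined)
  if (p < 0 || p > 1) stop_input("p must be in (0, 1]")
  if (is.na(E_c) || E_c <= 0 || E_c > C)
    stop_input("E_c must be in (0, C]")
  num <- C1 - p * C
  den <- p * (E_c - C)
  if (den == 0) {
    if (abs(num) <= 1e-9 * C1) return(list(raw = 0, estimate = 0,
                                           in_range = TRUE))
    return(undefined)
  }
  raw <- num / den
  if (abs(raw) <= 1e-9) raw <- 0
  if (abs(raw - 1) <= 1e-9) raw <- 1
  list(raw = raw, estimate = min(max(raw, 0), 1),
       in_range = raw >= 0 && raw <= 1)
}

#' Parity progression ratio table over a grid of truncation points
#'
#' Composes [interval_data()], [trunc_mean_interval()] and [ppr_point()]
#' into the standard reporting grid: one row per parity transition, one
#' column per long-truncation value `C`, plus a per-transition median across
#' the `C` grid (an even number of cells averages the central pair).
#' Cells with no women at the transition's parity, or with `p = 0`, are
#' missing rather than zero; a median computed over an incomplete row is
#' flagged.
#'
#' @param x A `cohort`.
#' @param transitions Integer vector of parity transitions (default `0:3`,
#'   i.e. marriage to first birth through third to fourth).
#' @param C_grid Long truncation points in months (default 60 to 120 by 12,
#'   i.e. 5 to 10 years).
#' @param C1 Short truncation in months (default 12).
#' @param open_denominator Passed to [interval_data()].
#' @return An object of class `ppr_table`: matrices `estimate` (clamped),
#'   `raw` and `in_range` of dimension transitions x grid, the vector
#'   `medians`, logical `median_complete`, and counts `n_closed`, `n_open`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_women = 400, seed = 7,
#'                                   interview_window = c(1, 420)))
#' ppr_table(coh)
#' @export
ppr_table <- function(x, transitions = 0:3,
                      C_grid = c(60, 72, 84, 96, 108, 120), C1 = 12,
                      open_denominator = c("within_C", "all")) {
  open_denominator <- match.arg(open_denominator)
  transitions <- as.integer(transitions)
  if (anyNA(transitions) || any(transitions < 0))
    stop_input("transitions must be non-negative integers")
  if (any(C_grid <= C1)) stop_input("every C in C_grid must exceed C1")

  rn <- sprintf("%d->%d", transitions, transitions + 1L)
  cn <- sprintf("C=%g", C_grid)
  est <- raw <- matrix(NA_real_, length(transitions), length(C_grid),
                       dimnames = list(rn, cn))
  inr <- matrix(NA, length(transitions), length(C_grid),
                dimnames = list(rn, cn))
  n_closed <- n_open <- matrix(0L, length(transitions), length(C_grid),
                               dimnames = list(rn, cn))

  for (r in seq_along(transitions)) {
    for (k in seq_along(C_grid)) {
      iv <- interval_data(x, transitions[r], C1 = C1, C = C_grid[k],
                          open_denominator = open_denominator)
      n_closed[r, k] <- length(iv$closed)
      n_open[r, k] <- iv$n_denominator
      if (!length(iv$closed) || is.na(iv$p) || iv$p == 0) next
      pt <- ppr_point(iv$p, trunc_mean_interval(iv$closed, C_grid[k]),
                      C1 = C1, C = C_grid[k])
      est[r, k] <- pt$estimate
      raw[r, k] <- pt$raw
      inr[r, k] <- pt$in_range
    }
  }

  medians <- ppr_medians(est)
  structure(list(estimate = est, raw = raw, in_range = inr,
                 medians = medians,
                 median_complete = !apply(is.na(est), 1, any),
                 n_closed = n_closed, n_open = n_open,
                 transitions = transitions, C_grid = C_grid, C1 = C1,
                 open_denominator = open_denominator),
            class = "ppr_table")
}

#' Per-transition medians of a parity-progression grid
#'
#' Median of each grid row across the truncation-point columns, the summary
#' conventionally reported alongside the grid. An even number of cells
#' yields the mean of the two central values; missing cells are dropped.
#'
#' @param x A `ppr_table` or a numeric matrix (transitions x C values).
#' @return Named numeric vector of row medians.
#' @export
ppr_medians <- function(x) {
  if (inherits(x, "ppr_table")) x <- x$estimate
  if (!is.matrix(x)) stop_input("x must be a ppr_table or a matrix")
  apply(x, 1, median, na.rm = TRUE)
}

#' @export
print.ppr_table <- function(x, digits = 3, ...) {
  cat(sprintf("Parity progression ratios (C1 = %g months, %s denominator)\n",
              x$C1, x$open_denominator))
  out <- cbind(round_half_up(x$estimate, digits),
               median = round_half_up(x$medians, digits))
  print(out, na.print = ".")
  if (any(!x$in_range, na.rm = TRUE))
    cat("note: raw estimates outside [0, 1] were clamped; see $raw\n")
  if (any(!x$median_complete))
    cat("note: medians over incomplete rows:",
        paste(rownames(x$estimate)[!x$median_complete], collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ppr_table <- function(x, ...) {
  grid <- expand.grid(transition = rownames(x$estimate),
                      C = x$C_grid, stringsAsFactors = FALSE)
  grid$estimate <- as.vector(x$estimate)
  grid$raw <- as.vector(x$raw)
  grid$in_range <- as.vector(x$in_range)
  grid$n_closed <- as.vector(x$n_closed)
  grid$n_open <- as.vector(x$n_open)
  grid
}

#' @export
plot.ppr_table <- function(x, ...) {
  matplot(x$C_grid, t(x$estimate), type = "b", pch = 19, lty = 1,
          xlab = "C (months)", ylab = "parity progression ratio",
          ylim = c(0, 1), ...)
  legend("bottomleft", legend = rownames(x$estimate), col = seq_len(nrow(x$estimate)),
         lty = 1, pch = 19, bty = "n")
  invisible(x)
}
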