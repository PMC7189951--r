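#' Expand a cohort to counting-process gap-time records
#'
#' Converts woman-level histories into the long format fitted by [pwp_gt()]:
#' the clock restarts at marriage and at every birth, and a woman is at risk
#' of the s-th birth only after her (s-1)-th. A woman of parity p contributes
#' one event record in each stratum `1..min(p, max_stratum)` with gap time
#' `t_s - t_{s-1}` (with `t_0 = 0` at marriage) and, if `p < max_stratum`, a
#' single censored record in stratum `p + 1` with gap time
#' `interview_time - t_p`. Covariates are carried over unchanged
#' (time-fixed).
#'
#' @param x A `cohort`.
#' @param max_stratum Highest birth order analysed (default 4, i.e. first to
#'   fourth deliveries).
#' @return A data frame of class `gap_data` with columns `woman_id`,
#'   `stratum`, `gap_time`, `event` (1 birth, 0 censored) and the covariate
#'   columns.
#' @examples
#' coh <- make_fixture("tiny8")
#' gaps <- expand_gaps(coh)
#' table(gaps$stratum, gaps$event)
#' @export
expand_gaps <- function(x, max_stratum = 4L) {
  validate_cohort(x)
  max_stratum <- as.integer(max_stratum)
  if (is.na(max_stratum) || max_stratum < 1L)
    stop_input("max_stratum must be a positive integer")

  p <- parity(x)
  n_event <- pmin(p, max_stratum)
  n_rows <- n_event + as.integer(p < max_stratum)

  idx <- rep.int(seq_len(nrow(x)), n_rows)
  stratum <- unlist(lapply(n_rows, seq_len), use.names = FALSE)
  event <- as.integer(stratum <= n_event[idx])

  gap <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    s <- stratum[k]
    prev <- if (s == 1L) 0 else x$birth_times[[i]][s - 1L]
    gap[k] <- if (event[k] == 1L) x$birth_times[[i]][s] - prev
              else x$interview_time[i] - prev
  }

  out <- data.frame(woman_id = x$woman_id[idx], stratum = stratum,
                    gap_time = gap, event = event, stringsAsFactors = FALSE)
  for (nm in .covariate_columns) out[[nm]] <- x[[nm]][idx]
  rownames(out) <- NULL
  class(out) <- c("gap_data", "data.frame")
  out
}

#' @export
print.gap_data <- function(x, ...) {
  cat(sprintf("<gap_data> %d records, %d women, strata 1-%d\n",
              nrow(x), length(unique(x$woman_id)), max(x$stratum)))
  tab <- table(stratum = x$stratum, event = x$event)
  print(tab)
  invisible(x)
}
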