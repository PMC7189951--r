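#' Stratified Cox partial log-likelihood for gap times
#'
#' Value, score vector and observed information of the partial likelihood of
#' the gap-time hazard model `h(u | x) = h0(u) exp(b'x)` for a single
#' stratum: subjects enter the risk set at gap time 0 and leave at their
#' event or censoring time, so the risk set at an event time `u` is every
#' record with `gap_time >= u`. Ties among event times are handled by the
#' Breslow (default) or Efron approximation. Derivatives are analytic.
#'
#' @param beta Coefficient vector (length `ncol(x)`).
#' @param time Gap times, months.
#' @param status 1 for an observed birth, 0 for censoring at interview.
#' @param x Design matrix (no intercept), one row per record.
#' @param ties `"breslow"` or `"efron"`.
#' @return List with `loglik` (scalar), `score` (length-p vector) and
#'   `information` (p x p observed information, i.e. minus the Hessian).
#' @examples
#' ll0 <- pwp_loglik(0, time = c(5, 9), status = c(1, 1),
#'                   x = matrix(c(1, 0)))
#' ll0$loglik  # -log(2): risk sets of size 2, then 1
#' @export
pwp_loglik <- function(beta, time, status, x, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  p <- ncol(x)
  n <- length(time)
  if (length(status) != n || nrow(x) != n)
    stop_input("time, status and x must agree in length")
  if (length(beta) != p) stop_input("beta has length %d, need %d",
                                    length(beta), p)
  if (!any(status == 1)) stop_input("no events in stratum: likelihood undefined")

  eta <- drop(x %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)

  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  S0 <- 0
  S1 <- numeric(p)
  S2 <- matrix(0, p, p)

  k <- 1
  while (k <= n) {
    u <- time[ord[k]]
    # admit everyone with gap time >= u to the running risk-set sums
    block <- integer(0)
    while (k <= n && time[ord[k]] == u) {
      i <- ord[k]
      S0 <- S0 + w[i]
      S1 <- S1 + w[i] * x[i, ]
      S2 <- S2 + w[i] * tcrossprod(x[i, ])
      block <- c(block, i)
      k <- k + 1
    }
    deaths <- block[status[block] == 1]
    d <- length(deaths)
    if (d == 0) next
    xd <- x[deaths, , drop = FALSE]
    loglik <- loglik + sum(eta[deaths])
    score <- score + colSums(xd)
    if (ties == "breslow" || d == 1) {
      loglik <- loglik - d * log(S0)
      score <- score - d * S1 / S0
      info <- info + d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      D0 <- sum(w[deaths])
      D1 <- colSums(w[deaths] * xd)
      D2 <- matrix(0, p, p)
      for (i in deaths) D2 <- D2 + w[i] * tcrossprod(x[i, ])
      for (j in seq_len(d) - 1) {
        f <- j / d
        E0 <- S0 - f * D0
        E1 <- S1 - f * D1
        E2 <- S2 - f * D2
        loglik <- loglik - log(E0)
        score <- score - E1 / E0
        info <- info + E2 / E0 - tcrossprod(E1 / E0)
      }
    }
  }
  list(loglik = unname(loglik), score = setNames(unname(score), colnames(x)),
       information = unname(info))
}

# Drop constant and linearly dependent design columns (rank-deficient fits
# are not identifiable); returns kept column indices.
full_rank_columns <- function(x) {
  keep <- which(apply(x, 2, function(col) diff(range(col)) > 0))
  if (!length(keep)) return(integer(0))
  qx <- qr(x[, keep, drop = FALSE])
  keep[qx$pivot[seq_len(qx$rank)]]
}

# Newton-Raphson with step-halving on one stratum.
fit_stratum <- function(time, status, x, ties, tol, max_iter) {
  p_all <- ncol(x)
  keep <- full_rank_columns(x)
  dropped <- setdiff(colnames(x), colnames(x)[keep])
  x <- x[, keep, drop = FALSE]
  p <- ncol(x)

  null_ll <- pwp_loglik(numeric(p), time, status, x, ties)$loglik
  beta <- numeric(p)
  ll <- null_ll
  converged <- p == 0
  monotone <- FALSE
  iter <- 0L
  deriv <- if (p > 0) pwp_loglik(beta, time, status, x, ties) else NULL

  while (p > 0 && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(deriv$information, deriv$score),
                     error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    new_beta <- beta + step
    new_deriv <- pwp_loglik(new_beta, time, status, x, ties)
    halvings <- 0L
    while (!is.finite(new_deriv$loglik) || new_deriv$loglik < ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 25L) break
      new_beta <- beta + (new_beta - beta) / 2
      new_deriv <- pwp_loglik(new_beta, time, status, x, ties)
    }
    beta <- new_beta
    deriv <- new_deriv
    ll <- deriv$loglik
    if (max(abs(beta)) > 20) { monotone <- TRUE; break }
    if (max(abs(deriv$score)) < tol) { converged <- TRUE; break }
  }
  # a "converged" optimum at an implausible magnitude is separation: the
  # score decays to zero along a monotone likelihood direction
  if (p > 0 && max(abs(beta)) > 10) monotone <- TRUE

  vcov <- if (p > 0 && !monotone)
    tryCatch(solve(deriv$information), error = function(e)
      matrix(NA_real_, p, p)) else matrix(NA_real_, p, p)
  if (p > 0) dimnames(vcov) <- list(colnames(x), colnames(x))
  se <- if (p > 0) sqrt(pmax(diag(vcov), 0)) else numeric(0)

  list(coef = setNames(beta, colnames(x)), se = setNames(se, colnames(x)),
       vcov = vcov, loglik = ll, loglik_null = null_ll,
       iterations = iter, converged = converged && !monotone,
       monotone = monotone, dropped = dropped,
       score_norm = if (p > 0) max(abs(deriv$score)) else 0,
       n = length(time), n_events = sum(status == 1))
}

#' Fit the Prentice-Williams-Peterson gap-time model
#'
#' Maximises the stratified Cox partial likelihood over gap-time records by
#' Newton-Raphson with step-halving. Each birth-order stratum has its own
#' baseline hazard; by default it also has its own coefficient vector (one
#' separate maximisation per delivery, matching the usual per-delivery
#' reporting), while `per_stratum = FALSE` estimates a single coefficient
#' vector shared across strata. Constant or collinear design columns are
#' dropped with a warning; monotone likelihood (separation) is detected via
#' diverging coefficients and flagged.
#'
#' @param formula RHS-only covariate formula, e.g. `~ woman_education +
#'   woman_employment`. Default: all nine standard covariates, with marriage
#'   ages continuous (per year) and the categorical covariates as dummies
#'   against their reference levels.
#' @param data A `gap_data` frame from [expand_gaps()], or a `cohort` (then
#'   expanded with `max_stratum`).
#' @param max_stratum Used only when `data` is a cohort (default 4).
#' @param ties Tie handling, `"breslow"` (default) or `"efron"`.
#' @param per_stratum Separate coefficients per stratum (default `TRUE`).
#' @param tol Convergence tolerance on the maximum absolute score component.
#' @param max_iter Newton-Raphson iteration cap.
#' @return An object of class `pwp_gt` with per-stratum components (`coef`,
#'   `se`, `vcov`, `loglik`, convergence diagnostics) and the encoding
#'   metadata needed by [wald_table()] and `predict()`.
#' @seealso [wald_table()], [pwp_loglik()]
#' @examples
#' gaps <- expand_gaps(simulate_cohort(sim_config(n_women = 150, seed = 3)))
#' fit <- pwp_gt(~ woman_employment + woman_age_at_marriage, gaps)
#' coef(fit)
#' @export
pwp_gt <- function(formula = NULL, data, max_stratum = 4L,
                   ties = c("breslow", "efron"), per_stratum = TRUE,
                   tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  if (inherits(data, "cohort")) data <- expand_gaps(data, max_stratum)
  if (!inherits(data, "gap_data"))
    stop_input("data must be a gap_data frame or a cohort")
  formula <- formula %||% .default_formula

  mf <- stats::model.frame(formula, data)
  X <- model.matrix(formula, mf)
  assign_map <- attr(X, "assign")[-1]
  X <- X[, -1, drop = FALSE]
  tl <- attr(terms(formula), "term.labels")
  xlevels <- stats::.getXlevels(terms(formula), mf)

  strata <- sort(unique(data$stratum))
  for (s in strata)
    if (!any(data$event[data$stratum == s] == 1))
      stop_input("stratum %d has no events: likelihood undefined", s)

  fits <- list()
  if (per_stratum) {
    for (s in strata) {
      rows <- data$stratum == s
      fits[[as.character(s)]] <- fit_stratum(
        data$gap_time[rows], data$event[rows], X[rows, , drop = FALSE],
        ties, tol, max_iter)
    }
  } else {
    fits[["all"]] <- fit_shared(data, X, strata, ties, tol, max_iter)
  }

  for (s in names(fits))
    if (length(fits[[s]]$dropped))
      warning(sprintf("stratum %s: dropped unidentifiable column(s): %s", s,
                      paste(fits[[s]]$dropped, collapse = ", ")),
              call. = FALSE)

  structure(list(strata = fits, stratum_levels = strata, ties = ties,
                 per_stratum = per_stratum, formula = formula,
                 term_labels = tl, assign = assign_map,
                 column_names = colnames(X), xlevels = xlevels,
                 tol = tol, call = match.call()),
            class = "pwp_gt")
}

# Shared-coefficient variant: one Newton-Raphson on the summed per-stratum
# partial likelihoods.
fit_shared <- function(data, X, strata, ties, tol, max_iter) {
  keep <- full_rank_columns(X)
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  eval_all <- function(beta) {
    tot <- list(loglik = 0, score = numeric(p),
                information = matrix(0, p, p))
    for (s in strata) {
      rows <- data$stratum == s
      d <- pwp_loglik(beta, data$gap_time[rows], data$event[rows],
                      X[rows, , drop = FALSE], ties)
      tot$loglik <- tot$loglik + d$loglik
      tot$score <- tot$score + d$score
      tot$information <- tot$information + d$information
    }
    tot
  }
  beta <- numeric(p)
  deriv <- eval_all(beta)
  null_ll <- ll <- deriv$loglik
  converged <- p == 0
  monotone <- FALSE
  iter <- 0L
  while (p > 0 && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(deriv$information, deriv$score),
                     error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    new_beta <- beta + step
    new_deriv <- eval_all(new_beta)
    halvings <- 0L
    while (!is.finite(new_deriv$loglik) || new_deriv$loglik < ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 25L) break
      new_beta <- beta + (new_beta - beta) / 2
      new_deriv <- eval_all(new_beta)
    }
    beta <- new_beta; deriv <- new_deriv; ll <- deriv$loglik
    if (max(abs(beta)) > 20) { monotone <- TRUE; break }
    if (max(abs(deriv$score)) < tol) { converged <- TRUE; break }
  }
  if (p > 0 && max(abs(beta)) > 10) monotone <- TRUE
  vcov <- if (p > 0 && !monotone)
    tryCatch(solve(deriv$information),
             error = function(e) matrix(NA_real_, p, p))
    else matrix(NA_real_, p, p)
  if (p > 0) dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = setNames(beta, colnames(X)),
       se = setNames(if (p > 0) sqrt(pmax(diag(vcov), 0)) else numeric(0),
                     colnames(X)),
       vcov = vcov, loglik = ll, loglik_null = null_ll, iterations = iter,
       converged = converged && !monotone, monotone = monotone,
       dropped = dropped,
       score_norm = if (p > 0) max(abs(deriv$score)) else 0,
       n = nrow(data), n_events = sum(data$event == 1))
}

#' Hazard-ratio report table
#'
#' Lays a fitted model out in the conventional per-delivery reporting shape:
#' one row per covariate level and stratum with hazard ratio
#' `exp(coefficient)`, its standard error, and the two-sided Wald p-value
#' from the normal approximation. Reference levels of categorical covariates
#' are included with hazard ratio 1 and blank SE/p; columns dropped as
#' unidentifiable appear with missing estimates.
#'
#' @param fit A `pwp_gt` fit.
#' @return Data frame with columns `stratum`, `variable`, `level`, `term`,
#'   `coef`, `HR`, `SE`, `z`, `p`, `reference`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "pwp_gt"))
  rows <- list()
  for (s in names(fit$strata)) {
    f <- fit$strata[[s]]
    for (v in seq_along(fit$term_labels)) {
      var <- fit$term_labels[v]
      lv <- fit$xlevels[[var]]
      if (!is.null(lv)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, variable = var, level = lv[1],
          term = paste0(var, lv[1]), coef = 0, HR = 1, SE = NA_real_,
          z = NA_real_, p = NA_real_, reference = TRUE,
          stringsAsFactors = FALSE)
        terms_v <- paste0(var, lv[-1])
        levels_v <- lv[-1]
      } else {
        terms_v <- fit$column_names[fit$assign == v]
        levels_v <- rep("", length(terms_v))
      }
      for (j in seq_along(terms_v)) {
        tm <- terms_v[j]
        b <- unname(f$coef[tm])
        se <- unname(f$se[tm])
        b <- if (tm %in% names(f$coef)) b else NA_real_
        se <- if (tm %in% names(f$se)) se else NA_real_
        z <- b / se
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, variable = var, level = levels_v[j], term = tm,
          coef = b, HR = exp(b), SE = se, z = z,
          p = 2 * pnorm(-abs(z)), reference = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pwp_gt <- function(x, digits = 3, ...) {
  cat(sprintf("PWP gap-time model (%s ties, %s coefficients)\n", x$ties,
              if (x$per_stratum) "per-stratum" else "shared"))
  for (s in names(x$strata)) {
    f <- x$strata[[s]]
    cat(sprintf("\nStratum %s: %d records, %d events, loglik %.3f%s\n", s,
                f$n, f$n_events, f$loglik,
                if (f$converged) "" else if (f$monotone)
                  "  [monotone likelihood]" else "  [NOT converged]"))
    if (length(f$coef)) {
      tab <- cbind(coef = f$coef, HR = exp(f$coef), SE = f$se,
                   z = f$coef / f$se,
                   p = 2 * pnorm(-abs(f$coef / f$se)))
      print(round(tab, digits))
    }
  }
  invisible(x)
}

#' @export
summary.pwp_gt <- function(object, ...) {
  structure(list(table = wald_table(object), ties = object$ties,
                 per_stratum = object$per_stratum,
                 converged = vapply(object$strata, `[[`, TRUE, "converged"),
                 loglik = vapply(object$strata, `[[`, 0, "loglik")),
            class = "summary.pwp_gt")
}

#' @export
print.summary.pwp_gt <- function(x, digits = 3, ...) {
  cat(sprintf("PWP gap-time model (%s ties); log partial likelihood: %s\n",
              x$ties, paste(round(x$loglik, 2), collapse = ", ")))
  tab <- x$table
  tab$HR <- round_half_up(tab$HR, 2)
  tab$SE <- round_half_up(tab$SE, 2)
  tab$p <- round_half_up(tab$p, 3)
  print(tab[, c("stratum", "variable", "level", "HR", "SE", "p")],
        na.print = "", row.names = FALSE)
  invisible(x)
}

#' @export
coef.pwp_gt <- function(object, ...) {
  out <- matrix(NA_real_, length(object$column_names),
                length(object$strata),
                dimnames = list(object$column_names, names(object$strata)))
  for (s in names(object$strata)) {
    b <- object$strata[[s]]$coef
    out[names(b), s] <- b
  }
  if (ncol(out) == 1L) drop(out) else out
}

#' @export
vcov.pwp_gt <- function(object, stratum = NULL, ...) {
  if (is.null(stratum)) stratum <- names(object$strata)[1]
  object$strata[[as.character(stratum)]]$vcov
}

#' @export
logLik.pwp_gt <- function(object, ...) {
  ll <- sum(vapply(object$strata, `[[`, 0, "loglik"))
  df <- sum(vapply(object$strata, function(f) length(f$coef), 0L))
  structure(ll, df = df, class = "logLik")
}

#' @export
predict.pwp_gt <- function(object, newdata, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  if (!all(c("stratum") %in% names(newdata)))
    stop_input("newdata must contain a 'stratum' column")
  X <- model.matrix(object$formula,
                    stats::model.frame(object$formula, newdata,
                                       xlev = object$xlevels))[, -1,
                                                              drop = FALSE]
  lp <- numeric(nrow(newdata))
  for (s in names(object$strata)) {
    rows <- if (object$per_stratum)
      newdata$stratum == as.integer(s) else rep(TRUE, nrow(newdata))
    b <- object$strata[[s]]$coef
    if (any(rows) && length(b))
      lp[rows] <- drop(X[rows, names(b), drop = FALSE] %*% b)
  }
  if (type == "risk") exp(lp) else lp
}
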