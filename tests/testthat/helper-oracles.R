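# Independent oracles and random-case generators shared across the suite.
# The oracles enumerate definitions literally and share no code with the
# package internals they check.

# Partial log-likelihood by direct enumeration: one term per event, risk set
# found by scanning all records (Breslow under ties).
naive_breslow_loglik <- function(beta, time, status, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Efron tie handling, written from the textbook formula.
naive_efron_loglik <- function(beta, time, status, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  ll <- 0
  for (u in unique(time[status == 1])) {
    D <- which(status == 1 & time == u)
    R <- which(time >= u)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (j in seq_len(d) - 1)
      ll <- ll - log(sum(exp(eta[R])) - (j / d) * sum(exp(eta[D])))
  }
  ll
}

# Central finite differences of a scalar-in / scalar-or-vector-out function.
numeric_gradient <- function(f, beta, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- replace(numeric(length(beta)), j, h)
    (f(beta + e) - f(beta - e)) / (2 * h)
  }, numeric(1))
}

# Random small gap-time data with deliberate ties (integer times).
random_tiny_gaps <- function(n_max = 8, p = 1) {
  n <- sample(2:n_max, 1)
  list(time = sample(1:6, n, replace = TRUE),
       status = pmax(rbinom(n, 1, 0.7), c(1, rep(0, n - 1))),
       x = matrix(round(rnorm(n * p), 2), n, p))
}

# A valid random cohort exercising every field, for round-trip and
# invariant properties.
random_cohort <- function(n) {
  par <- sample(0:7, n, replace = TRUE)
  bt <- lapply(par, function(p) if (p) cumsum(runif(p, 9, 80)) else numeric(0))
  it <- vapply(bt, function(b) (if (length(b)) max(b) else 0) + runif(1, 1, 200),
               numeric(1))
  sexes <- lapply(par, function(p) sample(c("male", "female"), p, replace = TRUE))
  cov <- data.frame(
    woman_age_at_marriage = runif(n, 14, 30),
    woman_education = sample(c("illiterate/primary", "secondary",
                               "high school", "academic"), n, replace = TRUE),
    woman_employment = sample(c("employed", "unemployed"), n, replace = TRUE),
    husband_age = runif(n, 18, 45),
    husband_education = sample(c("illiterate/primary", "secondary",
                                 "high school", "academic"), n, replace = TRUE),
    husband_employment = sample(c("employed", "unemployed"), n, replace = TRUE),
    stillbirth = sample(c("yes", "no"), n, replace = TRUE),
    age_first_pregnancy = sample(c("<=18", ">18"), n, replace = TRUE),
    income = sample(c("<=135", "135-270", ">=270"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  cohort(sprintf("r%03d", seq_len(n)), it, bt, sexes, cov)
}

# Cohort with an exact nested parity distribution (counts of women with at
# least 1..4 children out of n); covariates constant, gap times arbitrary.
cohort_from_counts <- function(n, at_least, le18_among_mothers = 0) {
  n_exact <- -diff(c(n, at_least, 0))            # women with exactly 0..4
  par <- rep(0:4, n_exact)
  bt <- lapply(par, function(p) if (p) seq(30, by = 54, length.out = p)
               else numeric(0))
  sexes <- lapply(par, function(p) rep("female", p))
  afp <- rep(">18", n)
  mothers <- which(par >= 1)
  if (le18_among_mothers) afp[mothers[seq_len(le18_among_mothers)]] <- "<=18"
  cov <- data.frame(
    woman_age_at_marriage = 20, woman_education = "secondary",
    woman_employment = "unemployed", husband_age = 25,
    husband_education = "secondary", husband_employment = "employed",
    stillbirth = "no", age_first_pregnancy = afp, income = "135-270",
    stringsAsFactors = FALSE
  )
  cohort(sprintf("c%04d", seq_len(n)), rep(400, n), bt, sexes, cov)
}

# Truncated mean oracle: exact integration of the empirical survival step
# function over [0, C] by summing rectangle areas between its jump points.
integrate_empirical_survival <- function(x, C) {
  breaks <- c(0, sort(unique(x[x < C])), C)
  heights <- vapply(head(breaks, -1), function(t) mean(x > t), numeric(1))
  sum(heights * diff(breaks))
}

grid_path <- function() {
  system.file("extdata", "ppr_grid_reference.csv", package = "birthgap")
}
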