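#' Shapiro-Wilk normality test
#'
#' Thin validated wrapper around [stats::shapiro.test()], used to check
#' normality of daily DI and distance series before the parametric battery.
#'
#' @param values numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000 finite values", call. = FALSE)
  if (stats::var(values) == 0)
    stop("degenerate input: sample is constant (zero variance)", call. = FALSE)
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Polynomial trend of a daily DI series
#'
#' Least-squares fit of `di = a0 + a1 t + a2 t^2 + ...` over hour-of-day,
#' degree 2 by default (the conventional quadratic trend test). Note a
#' quadratic has a single extremum and cannot represent a two-peak (M-shaped)
#' daily curve; `degree` is exposed for that reason, but the default follows
#' the standard battery.
#'
#' @param hours numeric abscissae (hour of day); at least `degree + 1`
#'   distinct values.
#' @param di_values numeric ordinates.
#' @param degree polynomial degree (default 2).
#' @return list with `coefficients` (named `a0`, `a1`, ...) and `r_squared`.
#' @export
quadratic_fit <- function(hours, di_values, degree = 2) {
  ok <- is.finite(hours) & is.finite(di_values)
  hours <- hours[ok]; di_values <- di_values[ok]
  if (length(unique(hours)) < degree + 1)
    stop(sprintf("need at least %d distinct abscissae for degree %d",
                 degree + 1, degree), call. = FALSE)
  if (stats::var(di_values) == 0) {
    co <- c(di_values[1], rep(0, degree))
    names(co) <- paste0("a", 0:degree)
    return(list(coefficients = co, r_squared = 0))
  }
  fit <- stats::lm(di_values ~ stats::poly(hours, degree, raw = TRUE))
  co <- unname(stats::coef(fit))
  names(co) <- paste0("a", 0:degree)
  # suppressWarnings: summary.lm warns on exact fits, which are legitimate here
  list(coefficients = co,
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

.check_groups <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  n_by <- table(groups)
  if (length(n_by) < 2)
    stop("need at least 2 groups", call. = FALSE)
  if (any(n_by < 2))
    stop(sprintf("every group needs >= 2 observations (offending: %s)",
                 paste(names(n_by)[n_by < 2], collapse = ", ")), call. = FALSE)
  list(values = values, groups = groups)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition via [stats::lm()]; unbalanced
#' groups (unequal monitoring days per month) are supported.
#'
#' @param values numeric observations.
#' @param groups parallel group labels.
#' @return list with `F`, `df_between`, `df_within`, `p`, `ms_within`,
#'   `group_means`, `group_n`.
#' @export
one_way_anova <- function(values, groups) {
  g <- .check_groups(values, groups)
  fac <- factor(g$groups)
  fit <- stats::lm(g$values ~ fac)
  an <- stats::anova(fit)
  list(F = an$`F value`[1],
       df_between = an$Df[1], df_within = an$Df[2],
       p = an$`Pr(>F)`[1],
       ms_within = an$`Mean Sq`[2],
       group_means = tapply(g$values, fac, mean),
       group_n = as.integer(table(fac)))
}

#' Duncan studentized-range quantile
#'
#' Duncan's significant range for a span of `p` ordered means at protection
#' level `1 - (1 - alpha)^(p - 1)`, computed from the studentized range
#' distribution: `qtukey((1 - alpha)^(p - 1), p, df)`.
#'
#' @param alpha nominal per-comparison significance level.
#' @param p span (number of means covered), >= 2.
#' @param df error degrees of freedom.
#' @return numeric quantile (vectorised over `p`).
#' @export
q_duncan <- function(alpha, p, df) {
  stats::qtukey((1 - alpha)^(p - 1), p, df)
}

#' Duncan's multiple range test
#'
#' Post-hoc comparison of group means after a one-way ANOVA, using Duncan's
#' stepwise significant ranges. Means are sorted descending; the critical
#' range for a span of `p` means is `q_duncan(alpha, p, df) *
#' sqrt(MSE / n_h)`, with `n_h` the harmonic mean of the two compared group
#' sizes (the Kramer extension for unbalanced groups, e.g. unequal monitoring
#' days per month). A span found non-significant protects all spans inside
#' it. The result is the usual compact letter display: groups sharing a
#' letter are not significantly different.
#'
#' @param values numeric observations.
#' @param groups parallel group labels.
#' @param alpha significance level (default 0.05).
#' @return an object of class `duncan_result`: `group_means` (sorted
#'   descending; ties kept in stable label order), `letters` (named character
#'   vector), `alpha`, `ms_within`, `df_within`, `group_n`, and the logical
#'   `nonsig` span matrix.
#' @export
duncan_mrt <- function(values, groups, alpha = 0.05) {
  an <- one_way_anova(values, groups)
  means <- an$group_means
  ns <- an$group_n
  names(ns) <- names(means)
  ord <- order(-means, names(means))    # descending; ties stable by label
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  mse <- an$ms_within
  dfw <- an$df_within
  nonsig <- diag(TRUE, k)
  protected <- matrix(FALSE, k, k)
  for (p in k:2) {
    rp <- q_duncan(alpha, p, dfw)
    for (i in seq_len(k - p + 1)) {
      j <- i + p - 1
      if (protected[i, j]) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
        next
      }
      n_h <- 2 / (1 / ns[i] + 1 / ns[j])
      crit <- rp * sqrt(mse / n_h)
      if (abs(means[i] - means[j]) <= crit) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
        if (p > 2)
          for (a in i:(j - 1)) for (b in (a + 1):j)
            protected[a, b] <- TRUE
      }
    }
  }
  # compact letter display from maximal non-significant runs
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1
    intervals[[i]] <- c(i, j)
  }
  keep <- vapply(seq_along(intervals), function(i) {
    !any(vapply(seq_along(intervals), function(j) {
      j != i && intervals[[j]][1] <= intervals[[i]][1] &&
        intervals[[j]][2] >= intervals[[i]][2]
    }, TRUE))
  }, TRUE)
  intervals <- unique(intervals[keep])
  letters_by_group <- stats::setNames(rep("", k), names(means))
  for (li in seq_along(intervals)) {
    rng <- intervals[[li]]
    for (g in rng[1]:rng[2])
      letters_by_group[g] <- paste0(letters_by_group[g], letters[li])
  }
  structure(list(group_means = means, letters = letters_by_group,
                 alpha = alpha, ms_within = mse, df_within = dfw,
                 group_n = ns, nonsig = nonsig),
            class = "duncan_result")
}

#' @export
print.duncan_result <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, MSE = %.4g, df = %d)\n",
              x$alpha, x$ms_within, x$df_within))
  df <- data.frame(mean = round(x$group_means, 4), n = x$group_n,
                   letters = x$letters)
  print(df)
  invisible(x)
}

#' Independent two-sample t-test
#'
#' Two-tailed independent t-test; Welch (unequal variances) by default,
#' Student's pooled-variance test with `equal_var = TRUE`.
#'
#' @param a,b numeric samples, each with >= 2 observations.
#' @param equal_var pool variances? Default `FALSE` (Welch).
#' @return list with `t`, `df`, `p`, `two_tailed = TRUE`.
#' @export
independent_t_test <- function(a, b, equal_var = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need >= 2 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      stop("degenerate input: both samples constant and equal", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = equal_var, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, two_tailed = TRUE)
}
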