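#' Behavioral summary table of a cohort
#'
#' One row per subject: sex, age, realized Go and NoGo accuracy (%) from
#' the trial tables, and the mean reaction time of correct Go trials (ms).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @return Data frame of class `behavior_table`.
#' @export
behavior_table <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    b <- s$behavior
    go <- b$trial_type == "Go"
    data.frame(
      id = s$id, sex = s$sex, age = s$age,
      go_acc = 100 * mean(b$correct[go]),
      nogo_acc = 100 * mean(b$correct[!go]),
      rt_ms = mean(b$rt_ms[go & b$correct], na.rm = TRUE)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F df1 / (F df1 + df2)`, algebraically identical to
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param F_stat F value.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared.
#' @export
eta_p_from_f <- function(F_stat, df1, df2) {
  F_stat * df1 / (F_stat * df1 + df2)
}

#' Repeated-measures ANOVA: inhibition (Go vs NoGo) by sex, age-adjusted
#'
#' Mixed-design analysis of accuracy with a two-level within-subject factor
#' (inhibition: Go vs NoGo), sex as the between-subject factor and age as a
#' covariate. With a two-level within factor the within-subject effects
#' reduce exactly to a regression of the per-subject Go-NoGo difference on
#' the (centered) between-subject terms: the intercept F is the inhibition
#' main effect with df = (1, n - 3), and the sex coefficient is the
#' inhibition-by-sex interaction. The between-subject sex effect comes from
#' the same regression on the per-subject means. Effect sizes are partial
#' eta squared.
#'
#' @param table A [behavior_table()].
#' @param age_covariate Include age as covariate (default `TRUE`).
#' @return Data frame: one row per effect (`inhibition`, `sex`,
#'   `inhibition:sex`) with F, df1, df2, p and `eta_p_sq`.
#' @export
rm_anova_inhibition_by_sex <- function(table, age_covariate = TRUE) {
  n <- nrow(table)
  two_sex <- length(unique(table$sex)) == 2
  if (!two_sex) {
    warning("single-sex table: between-subject factor dropped")
  }
  diffs <- table$go_acc - table$nogo_acc
  means <- (table$go_acc + table$nogo_acc) / 2
  Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (two_sex) {
    sexc <- ifelse(table$sex == "female", 0.5, -0.5)
    Z <- cbind(Z, sex = sexc - mean(sexc))
  }
  if (age_covariate) Z <- cbind(Z, age = table$age - mean(table$age))

  eff_row <- function(y, col, name) {
    fit <- stats::lm.fit(Z, y)
    df2 <- n - ncol(Z)
    s2 <- sum(fit$residuals^2) / df2
    XtXi <- solve(crossprod(Z))
    b <- fit$coefficients[col]
    Fv <- if (abs(b) < 1e-12) 0 else unname(b^2 / (XtXi[col, col] * s2))
    data.frame(effect = name, F = Fv, df1 = 1, df2 = df2,
               p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
               eta_p_sq = eta_p_from_f(Fv, 1, df2))
  }
  out <- eff_row(diffs, "(Intercept)", "inhibition")
  if (two_sex) {
    out <- rbind(out,
                 eff_row(means, "sex", "sex"),
                 eff_row(diffs, "sex", "inhibition:sex"))
  }
  rownames(out) <- NULL
  out
}

#' Cohen's d from printed means and standard errors
#'
#' Pooled-SD standardized mean difference
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)` with `s = sem * sqrt(n)`.
#'
#' @param mean1,sem1,mean2,sem2 Group means and standard errors.
#' @param n Sample size underlying the SEMs.
#' @return Cohen's d.
#' @export
cohens_d_pooled <- function(mean1, sem1, mean2, sem2, n) {
  stopifnot(n >= 2, sem1 > 0, sem2 > 0)
  s1 <- sem1 * sqrt(n)
  s2 <- sem2 * sqrt(n)
  pooled <- sqrt((s1^2 + s2^2) / 2)
  if (pooled == 0) stop("zero pooled standard deviation")
  (mean1 - mean2) / pooled
}

#' Sex comparisons of accuracy and reaction time
#'
#' Two-group comparisons (female vs male) of Go accuracy, NoGo accuracy and
#' correct-Go reaction time, age-adjusted by default (linear model with a
#' centered sex contrast and centered age).
#'
#' @param table A [behavior_table()].
#' @param age_adjust Adjust for age.
#' @return Data frame: measure, difference (female - male), t, df, p.
#' @export
sex_comparison <- function(table, age_adjust = TRUE) {
  stopifnot(length(unique(table$sex)) == 2)
  if (min(table(table$sex)) < 2) stop("each sex group needs >= 2 subjects")
  sexc <- ifelse(table$sex == "female", 1, 0)
  out <- lapply(c("go_acc", "nogo_acc", "rt_ms"), function(m) {
    dat <- data.frame(y = table[[m]], sexc = sexc,
                      age = table$age - mean(table$age))
    fml <- if (age_adjust) y ~ sexc + age else y ~ sexc
    fit <- stats::lm(fml, dat)
    sm <- summary(fit)$coefficients
    data.frame(measure = m, difference = sm["sexc", 1],
               t = sm["sexc", 3], df = fit$df.residual,
               p = sm["sexc", 4])
  })
  do.call(rbind, out)
}
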