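# Shared group-comparison machinery: every p-value in the pipeline goes
# through run_comparison() with an explicit ComparisonSpec.

#' Specify a group comparison
#'
#' All testing is two-tailed at alpha = 0.05; the unit of analysis (animal,
#' cell, bout, event) is declared explicitly because different assays use
#' different granularities.
#'
#' @param test one of `"unpaired_t"`, `"paired_t"`, `"two_way_anova"`,
#'   `"ks_two_sample"`, `"pearson"`.
#' @param alpha significance level (default 0.05).
#' @param unit unit of analysis label.
#' @param measure name of the measured quantity (bookkeeping).
#' @return a `septodg_comparison_spec`.
#' @export
comparison_spec <- function(test = c("unpaired_t", "paired_t",
                                     "two_way_anova", "ks_two_sample",
                                     "pearson"),
                            alpha = 0.05, unit = "animal", measure = "") {
  test <- match.arg(test)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(test = test, alpha = alpha, tails = 2, unit = unit,
                 measure = measure),
            class = "septodg_comparison_spec")
}

comparison_row <- function(spec, statistic, df, p, n1, n2, mean1, mean2,
                           sem1 = NA, sem2 = NA, note = "") {
  data.frame(measure = spec$measure, test = spec$test, unit = spec$unit,
             statistic = statistic, df = df, p = p,
             n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2,
             sem1 = sem1, sem2 = sem2,
             sig = if (is.na(p)) NA else p <= spec$alpha,
             flag = if (is.na(p)) "undefined"
                    else if (p > spec$alpha) "n.s" else "*",
             note = note, stringsAsFactors = FALSE)
}

#' Run a declared group comparison
#'
#' Dispatches on `spec$test`: unpaired two-tailed Student t, paired t,
#' two-sample Kolmogorov-Smirnov on pooled empirical CDFs, Pearson
#' correlation, or two-way ANOVA (Type II).  Degenerate inputs (zero
#' variance, insufficient n) are reported as undefined rows, never raised
#' as errors, so exclusion bookkeeping can proceed.
#'
#' @param data for `unpaired_t` / `ks_two_sample`: data.frame
#'   (value, group) with exactly two groups; for `paired_t` / `pearson`:
#'   data.frame (x, y); for `two_way_anova`: data.frame (value, a, b).
#' @param spec a [comparison_spec()].
#' @return a one-row (ANOVA: multi-row) data.frame of results.
#' @export
run_comparison <- function(data, spec) {
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  switch(spec$test,
    unpaired_t = {
      gl <- unique(data$group)
      if (length(gl) != 2) stop("exactly two groups required", call. = FALSE)
      x <- data$value[data$group == gl[1]]
      y <- data$value[data$group == gl[2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 2 || length(y) < 2)
        return(comparison_row(spec, NA, NA, NA, length(x), length(y),
                              mean(x), mean(y), note = "insufficient n"))
      if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
        return(comparison_row(spec, NA, NA, if (mean(x) == mean(y)) 1 else NA,
                              length(x), length(y), mean(x), mean(y),
                              note = "zero variance"))
      tt <- stats::t.test(x, y, var.equal = TRUE, alternative = "two.sided")
      comparison_row(spec, unname(tt$statistic), unname(tt$parameter),
                     tt$p.value, length(x), length(y), mean(x), mean(y),
                     sem(x), sem(y))
    },
    paired_t = {
      ok <- is.finite(data$x) & is.finite(data$y)
      x <- data$x[ok]; y <- data$y[ok]
      if (length(x) < 2)
        return(comparison_row(spec, NA, NA, NA, length(x), length(x),
                              mean(x), mean(y), note = "insufficient n"))
      d <- x - y
      if (stats::sd(d) == 0)
        return(comparison_row(spec, if (all(d == 0)) 0 else NA,
                              length(d) - 1, if (all(d == 0)) 1 else NA,
                              length(x), length(y), mean(x), mean(y),
                              note = "zero variance of differences"))
      tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
      comparison_row(spec, unname(tt$statistic), unname(tt$parameter),
                     tt$p.value, length(x), length(y), mean(x), mean(y),
                     sem(x), sem(y))
    },
    ks_two_sample = {
      gl <- unique(data$group)
      if (length(gl) != 2) stop("exactly two groups required", call. = FALSE)
      x <- data$value[data$group == gl[1]]
      y <- data$value[data$group == gl[2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (!length(x) || !length(y))
        return(comparison_row(spec, NA, NA, NA, length(x), length(y),
                              NA, NA, note = "empty sample"))
      kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      comparison_row(spec, unname(kt$statistic), NA, kt$p.value,
                     length(x), length(y), mean(x), mean(y), sem(x), sem(y))
    },
    pearson = {
      ok <- is.finite(data$x) & is.finite(data$y)
      x <- data$x[ok]; y <- data$y[ok]
      if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
        return(comparison_row(spec, NA, NA, NA, length(x), length(x),
                              mean(x), mean(y), note = "undefined r"))
      ct <- stats::cor.test(x, y, method = "pearson")
      comparison_row(spec, unname(ct$estimate), unname(ct$parameter),
                     ct$p.value, length(x), length(x), mean(x), mean(y))
    },
    two_way_anova = {
      res <- anova_type2(data$value, factor(data$a), factor(data$b))
      res$measure <- spec$measure; res$unit <- spec$unit
      res
    })
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Main effects are tested against the model containing the other main
#' effect (Type II), the interaction against the additive model; all F
#' ratios use the full-model residual mean square.  Suited to unbalanced
#' designs such as unequal cell counts per genotype.
#'
#' @param y response vector.
#' @param A,B factors.
#' @param names labels for the three effect rows.
#' @return data.frame (effect, df, sumsq, F, p, sig).
#' @export
anova_type2 <- function(y, A, B, names = c("A", "B", "A:B")) {
  if (nlevels(A) < 2 || nlevels(B) < 2)
    stop("both factors need at least 2 levels", call. = FALSE)
  rss <- function(fml) sum(stats::resid(stats::lm(fml))^2)
  r_full <- stats::lm(y ~ A * B)
  rss_full <- sum(stats::resid(r_full)^2)
  df_full <- r_full$df.residual
  ms_full <- rss_full / df_full
  ss_a <- rss(y ~ B) - rss(y ~ A + B)
  ss_b <- rss(y ~ A) - rss(y ~ A + B)
  ss_ab <- rss(y ~ A + B) - rss_full
  df <- c(nlevels(A) - 1, nlevels(B) - 1,
          (nlevels(A) - 1) * (nlevels(B) - 1))
  ss <- c(ss_a, ss_b, ss_ab)
  Fv <- (ss / df) / ms_full
  p <- stats::pf(Fv, df, df_full, lower.tail = FALSE)
  data.frame(effect = names, df = df, df_resid = df_full, sumsq = ss,
             F = Fv, p = p, sig = p <= 0.05,
             flag = ifelse(p <= 0.05, "*", "n.s"),
             stringsAsFactors = FALSE)
}
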