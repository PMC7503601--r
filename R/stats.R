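test_result <- function(test_name, statistic, df, p_value,
                        estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                        correction_applied = FALSE, note = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p_value = unname(p_value),
                 estimate = unname(estimate), conf_int = unname(conf_int),
                 correction_applied = correction_applied, note = note),
            class = "adherence_test")
}

#' @export
print.adherence_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = "; ")
  cat(sprintf("%s: statistic = %.4g (df %s), p = %.4g%s\n", x$test_name,
              x$statistic, dfs, x$p_value,
              if (isTRUE(x$correction_applied)) " [corrected]" else ""))
  if (!all(is.na(x$conf_int)))
    cat(sprintf("  estimate %.4g (95%% CI %.4g, %.4g)\n",
                x$estimate, x$conf_int[1], x$conf_int[2]))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed-skewness and transformed-kurtosis z statistics
#' into K2 = z_s^2 + z_k^2, referred to a chi-squared distribution with
#' 2 df. Valid for n >= 8 (below that the kurtosis transform is undefined).
#'
#' @param x Numeric vector, n >= 8.
#' @return An `adherence_test` with the K2 statistic and p-value; `note`
#'   carries the component z values.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance input", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  # skewness transform (D'Agostino 1970)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  z_k <- (1 - 2 / (9 * a) -
            sign(denom) * abs((1 - 2 / a) / abs(denom))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z_s^2 + z_k^2
  test_result("D'Agostino-Pearson K2", k2, 2,
              stats::pchisq(k2, 2, lower.tail = FALSE),
              note = sprintf("z_skew = %.4f, z_kurt = %.4f", z_s, z_k))
}

#' Normality gate
#'
#' Classifies a sample as `gaussian` or `non_gaussian` using the
#' D'Agostino-Pearson omnibus test at `alpha`. Samples below the test's
#' validity floor (n < 8) or with zero variance are classified
#' `non_gaussian` with a warning/flag, steering downstream dispatch to the
#' nonparametric branch.
#'
#' @param x Numeric vector.
#' @param alpha Gate level (default 0.05).
#' @return List: `class` (`"gaussian"`/`"non_gaussian"`), `p_value`,
#'   `zero_variance`, `too_small`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) >= 2 && stats::sd(x) == 0)
    return(list(class = "non_gaussian", p_value = NA_real_,
                zero_variance = TRUE, too_small = FALSE))
  if (length(x) < 8) {
    warning("n < 8: below the omnibus test's validity floor; treating as non-Gaussian")
    return(list(class = "non_gaussian", p_value = NA_real_,
                zero_variance = FALSE, too_small = TRUE))
  }
  t <- dagostino_pearson(x)
  list(class = if (t$p_value >= alpha) "gaussian" else "non_gaussian",
       p_value = t$p_value, zero_variance = FALSE, too_small = FALSE)
}

#' Normality-gated paired comparison
#'
#' Two-level repeated measures: paired t-test when the within-pair
#' differences pass the normality gate, Wilcoxon signed-rank otherwise.
#' The t branch reports the mean difference (a - b) with its 95% CI.
#'
#' @param a,b Matched numeric vectors (n >= 3).
#' @param labels Length-2 character labels for reporting.
#' @return An `adherence_test`; `note` records the dispatch.
#' @export
paired_compare <- function(a, b, labels = c("a", "b")) {
  if (length(a) != length(b)) stop("paired vectors must match in length",
                                   call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(test_result("paired t-test", 0, length(d) - 1, 1, estimate = 0,
                       conf_int = c(0, 0), note = "all differences zero"))
  gate <- suppressWarnings(normality_gate(d))
  if (gate$class == "gaussian") {
    tt <- stats::t.test(a, b, paired = TRUE)
    test_result("paired t-test", tt$statistic, tt$parameter, tt$p.value,
                estimate = tt$estimate, conf_int = as.numeric(tt$conf.int),
                note = sprintf("differences Gaussian (gate p = %.3f)", gate$p_value))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    test_result("Wilcoxon signed-rank", wt$statistic, NA_real_, wt$p.value,
                estimate = stats::median(d),
                note = "differences non-Gaussian; nonparametric branch")
  }
}

long_to_wide <- function(data) {
  data <- data[stats::complete.cases(data[c("id", "time", "value")]), ]
  data$time <- if (is.factor(data$time)) droplevels(data$time)
    else factor(data$time, levels = unique(data$time))
  wide <- stats::reshape(data[c("id", "time", "value")], direction = "wide",
                         idvar = "id", timevar = "time")
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

#' Normality-gated one-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA over the `time` factor. Each time cell is
#' normality-gated; if any cell fails, the Friedman test is used instead.
#' With three or more levels, sphericity is assessed by Mauchly's test and
#' Greenhouse-Geisser degrees-of-freedom correction is applied when
#' violated (p < 0.05).
#'
#' @param data Long data frame with columns `id`, `time`, `value`;
#'   incomplete cases dropped.
#' @param gate_alpha Level of the per-cell normality gate.
#' @return An `adherence_test` (F with possibly fractional df, or the
#'   Friedman chi-squared).
#' @export
rm_anova <- function(data, gate_alpha = 0.05) {
  wide <- long_to_wide(data)
  if (nrow(wide) < 2) stop("insufficient data: < 2 complete cases", call. = FALSE)
  times <- setdiff(names(wide), "id")
  k <- length(times)
  ym <- as.matrix(wide[times])
  if (all(apply(ym, 1, function(r) all(r == r[1]))))
    return(test_result("RM-ANOVA", 0, c(k - 1, (k - 1) * (nrow(ym) - 1)), 1,
                       note = "no within-subject variation"))
  gates <- apply(ym, 2, function(col)
    suppressWarnings(normality_gate(col, gate_alpha))$class)
  if (any(gates == "non_gaussian")) {
    fr <- stats::friedman.test(ym)
    return(test_result("Friedman", fr$statistic, fr$parameter, fr$p.value,
                       note = "normality gate failed in at least one cell"))
  }
  mlm <- stats::lm(ym ~ 1)
  av <- suppressWarnings(summary(car::Anova(
    mlm, idata = data.frame(time = factor(times, levels = times)),
    idesign = ~time, type = 3), multivariate = FALSE))
  uni <- av$univariate.tests
  f <- uni["time", "F value"]
  df1 <- uni["time", "num Df"]; df2 <- uni["time", "den Df"]
  p <- uni["time", "Pr(>F)"]
  gg <- FALSE
  if (k > 2) {
    mauchly_p <- av$sphericity.tests["time", "p-value"]
    if (is.finite(mauchly_p) && mauchly_p < 0.05) {
      eps <- av$pval.adjustments["time", "GG eps"]
      df1 <- df1 * eps; df2 <- df2 * eps
      p <- av$pval.adjustments["time", "Pr(>F[GG])"]
      gg <- TRUE
    }
  }
  test_result("RM-ANOVA", f, c(df1, df2), p, correction_applied = gg,
              note = if (gg) "Greenhouse-Geisser corrected (Mauchly p < 0.05)")
}

#' Two-way mixed ANOVA with simple-effect follow-ups
#'
#' The time-by-group design: `time` within subjects (2 levels), `group`
#' between subjects (2 levels). Returns the interaction, time, and group
#' tests (type-III sums of squares); when the interaction is significant at
#' `follow_alpha`, simple main effects are added: between-group comparisons
#' at each time (Welch-corrected when Levene's test flags unequal
#' variances) and within-group paired t-tests.
#'
#' @param data Long data frame with columns `id`, `time`, `group`, `value`.
#' @param follow_alpha Interaction significance level gating the follow-ups
#'   (default 0.05). Follow-ups are reported uncorrected for multiplicity,
#'   with an optional `bonferroni` switch.
#' @param bonferroni Apply Bonferroni correction across the follow-up
#'   simple effects (default FALSE).
#' @return List of class `mixed_anova_result`: `interaction`, `time`,
#'   `group` (each an `adherence_test`), and `simple_effects` (named list,
#'   empty when the interaction is not significant).
#' @export
mixed_anova <- function(data, follow_alpha = 0.05, bonferroni = FALSE) {
  data <- data[stats::complete.cases(data[c("id", "time", "group", "value")]), ]
  data$group <- factor(data$group)
  if (nlevels(data$group) != 2) stop("exactly 2 groups required", call. = FALSE)
  gmap <- unique(data[c("id", "group")])
  if (any(table(gmap$id) > 1)) stop("group must be constant within id", call. = FALSE)
  wide <- long_to_wide(data)
  wide$group <- gmap$group[match(wide$id, gmap$id)]
  times <- setdiff(names(wide), c("id", "group"))
  if (length(times) != 2) stop("exactly 2 time levels required", call. = FALSE)
  if (min(table(wide$group)) < 2)
    stop("insufficient data: a group has < 2 complete cases", call. = FALSE)
  ym <- as.matrix(wide[times])
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- stats::lm(ym ~ group, data = wide)
  av <- suppressWarnings(summary(car::Anova(
    mlm, idata = data.frame(time = factor(times, levels = times)),
    idesign = ~time, type = 3), multivariate = FALSE))
  uni <- av$univariate.tests
  grab <- function(term, name) {
    ss_err <- uni[term, "Error SS"]
    if (uni[term, "Sum Sq"] < 1e-12 && ss_err < 1e-12)
      return(test_result(name, 0, c(uni[term, "num Df"], uni[term, "den Df"]), 1,
                         note = "degenerate: no variation"))
    test_result(name, uni[term, "F value"],
                c(uni[term, "num Df"], uni[term, "den Df"]),
                uni[term, "Pr(>F)"])
  }
  res <- list(interaction = grab("group:time", "mixed ANOVA interaction"),
              time = grab("time", "mixed ANOVA time"),
              group = grab("group", "mixed ANOVA group"),
              simple_effects = list())
  if (is.finite(res$interaction$p_value) &&
      res$interaction$p_value < follow_alpha) {
    se <- list()
    n_tests <- length(times) + nlevels(wide$group)
    adj <- function(p) if (bonferroni) min(1, p * n_tests) else p
    for (tm in times) {
      lev_p <- car::leveneTest(wide[[tm]], wide$group)[1, "Pr(>F)"]
      welch <- is.finite(lev_p) && lev_p < 0.05
      tt <- stats::t.test(wide[[tm]] ~ wide$group, var.equal = !welch)
      se[[paste0("between_at_", tm)]] <- test_result(
        if (welch) "Welch t-test" else "Student t-test",
        tt$statistic, tt$parameter, adj(tt$p.value),
        estimate = diff(rev(tt$estimate)),
        conf_int = as.numeric(tt$conf.int),
        correction_applied = bonferroni,
        note = if (welch) "Levene violation: Welch df")
    }
    for (g in levels(wide$group)) {
      sub <- wide[wide$group == g, ]
      if (nrow(sub) >= 3 && stats::sd(sub[[times[1]]] - sub[[times[2]]]) > 0) {
        tt <- stats::t.test(sub[[times[1]]], sub[[times[2]]], paired = TRUE)
        se[[paste0("within_", g)]] <- test_result(
          "paired t-test", tt$statistic, tt$parameter, adj(tt$p.value),
          estimate = tt$estimate, conf_int = as.numeric(tt$conf.int),
          correction_applied = bonferroni)
      }
    }
    res$simple_effects <- se
  }
  class(res) <- "mixed_anova_result"
  res
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  for (nm in c("interaction", "time", "group")) print(x[[nm]])
  if (length(x$simple_effects)) {
    cat("simple effects:\n")
    for (nm in names(x$simple_effects)) {
      cat("  ", nm, ": ", sep = "")
      print(x$simple_effects[[nm]])
    }
  }
  invisible(x)
}

#' Pearson correlation with t-transform p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), finite, each with
#'   non-zero variance.
#' @return An `adherence_test` with r as the estimate and the two-tailed p
#'   from the t transform with n - 2 df.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must match in length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result("Pearson correlation", ct$statistic, ct$parameter, ct$p.value,
              estimate = ct$estimate, conf_int = as.numeric(ct$conf.int))
}
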