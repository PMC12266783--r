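#' Two-way ANOVA with interaction
#'
#' Factorial analysis of variance with interaction, following the study
#' design's conventions: classical sequential (Type I) sums of squares for
#' balanced designs, Type II for unbalanced ones (the type used is recorded
#' in the result). Both limbs of an animal are treated as independent
#' observations.
#'
#' @param values numeric response (e.g. DNAmAGE in weeks).
#' @param treatment,injury factors (>= 2 levels each, >= 1 obs per cell).
#' @return data.frame with term, ss, df, statistic (F), p; attribute
#'   `ss_type` is "I" or "II".
#' @export
two_way_anova <- function(values, treatment, injury) {
  treatment <- factor(treatment); injury <- factor(injury)
  if (nlevels(treatment) < 2L || nlevels(injury) < 2L)
    stop("both factors need >= 2 levels")
  cells <- table(treatment, injury)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("empty design cell: treatment=%s, injury=%s",
                 rownames(cells)[empty[1L]], colnames(cells)[empty[2L]]))
  }
  balanced <- length(unique(as.vector(cells))) == 1L
  dat <- data.frame(y = values, a = treatment, b = injury)
  fit <- stats::lm(y ~ a * b, data = dat)
  # a perfect (zero-residual) fit is handled explicitly below
  muffle_perfect_fit <- function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  }
  if (balanced) {
    av <- withCallingHandlers(stats::anova(fit),
                              warning = muffle_perfect_fit)
    ss <- av[["Sum Sq"]]; df <- av[["Df"]]
    type <- "I"
  } else {
    av <- withCallingHandlers(car::Anova(fit, type = 2),
                              warning = muffle_perfect_fit)
    ss <- av[["Sum Sq"]]; df <- av[["Df"]]
    type <- "II"
  }
  ms_res <- ss[4L] / df[4L]
  f <- ss[1:3] / df[1:3] / ms_res
  p <- stats::pf(f, df[1:3], df[4L], lower.tail = FALSE)
  # a design with (numerically) zero variance everywhere: F = 0, p = 1
  tol <- 1e-12 * max(1, sum(ss))
  degenerate <- !is.finite(f) | (ss[1:3] < tol & ss[4L] < tol)
  f[degenerate] <- 0
  p[degenerate] <- 1
  out <- data.frame(
    term = c("treatment", "injury", "treatment:injury", "residuals"),
    ss = ss, df = df, statistic = c(f, NA), p = c(p, NA),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "ss_type") <- type
  out
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range based pairwise comparisons using the one-way ANOVA
#' residual mean square.
#'
#' @param values numeric response.
#' @param groups grouping factor (each group n >= 2).
#' @param alpha family-wise level for the confidence intervals.
#' @return data.frame: comparison, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  data.frame(comparison = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-tailed unpaired t-test
#'
#' Welch degrees of freedom by default; pooled-variance option. When both
#' groups are constant with equal means the statistic is degenerate and
#' (t = 0, p = 1) is returned with a message.
#'
#' @param values_a,values_b numeric samples (each n >= 2).
#' @param var_equal pool the variances.
#' @return list: t, df, p.
#' @export
unpaired_t <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      message("both groups constant with equal means; returning t=0, p=1")
      return(list(t = 0, df = length(values_a) + length(values_b) - 2, p = 1))
    }
    return(list(t = sign(mean(values_a) - mean(values_b)) * Inf,
                df = length(values_a) + length(values_b) - 2, p = 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, neither constant).
#' @return list: r, p, n.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need n >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p = unname(ht$p.value), n = length(x))
}
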