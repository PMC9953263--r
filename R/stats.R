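# Group-comparison statistics: per-group normality screening
# (D'Agostino-Pearson omnibus K-squared), then either one-way ANOVA with
# Tukey HSD or Kruskal-Wallis with Dunn's multiple comparisons versus
# control, with figure-legend significance tiers.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's z) and
#' kurtosis (Anscombe-Glynn's z) into the omnibus statistic
#' `K^2 = z_skew^2 + z_kurt^2`, referred to a chi-squared distribution
#' with 2 degrees of freedom. Requires at least 8 observations.
#'
#' @param x Numeric sample.
#' @return List with `statistic` (K^2), `p.value`, `z_skew`, `z_kurt`,
#'   `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson test needs at least 8 observations",
         call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(statistic = Inf, p.value = 0, z_skew = Inf, z_kurt = Inf,
                n = n))
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  g2 <- m4 / m2^2
  eg2 <- 3 * (n - 1) / (n + 1)
  vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eg2) / sqrt(vg2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2,
       p.value = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

# Significance tier at the figure-legend convention.
significance_tier <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

# Dunn's rank-based multiple comparisons versus a control group, with
# tie correction and Bonferroni adjustment over the k-1 comparisons.
dunn_vs_control <- function(values, groups, control) {
  n_tot <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  lev <- unique(groups)
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  others <- setdiff(lev, control)
  z <- vapply(others, function(g) {
    (rbar[[g]] - rbar[[control]]) /
      sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
             (1 / ns[[g]] + 1 / ns[[control]]))
  }, numeric(1))
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- pmin(p * length(others), 1)
  data.frame(group = others,
             estimate = vapply(others, function(g)
               rbar[[g]] - rbar[[control]], numeric(1)),
             statistic = z, p_unadjusted = p, p_adjusted = p_adj,
             tier = significance_tier(p_adj), row.names = NULL)
}

#' Compare treatment groups against a control
#'
#' Screens every group with the D'Agostino-Pearson normality test at
#' `alpha`. If all groups pass (and are large enough to test, n >= 8),
#' the family is compared by one-way ANOVA followed by Tukey's HSD;
#' otherwise by Kruskal-Wallis followed by Dunn's multiple comparisons.
#' A single failing group switches the whole family to the
#' nonparametric branch. Pairwise results are reported against the
#' control group with adjusted p-values and the figure-legend
#' significance tiers (* <= 0.05, ** <= 0.01, *** <= 0.001,
#' **** <= 0.0001).
#'
#' @param measurements Named list of numeric vectors (one per group), or
#'   a `data.frame` with columns `value` and `group`.
#' @param control Name of the control group (default: first group).
#' @param alpha Normality-screen significance level (default 0.05).
#' @return Object of class `group_comparison`: list with `summary`
#'   (per-group n / mean / SD / normality p), `method`, `statistic`,
#'   `p.value` (omnibus), and `pairwise` (vs-control table with
#'   `p_adjusted` and `tier`).
#' @export
compare_groups <- function(measurements, control = NULL, alpha = 0.05) {
  if (is.data.frame(measurements))
    measurements <- split(measurements$value, measurements$group)
  if (length(measurements) < 3L)
    stop("at least 3 groups are required", call. = FALSE)
  ns <- vapply(measurements, length, integer(1))
  if (any(ns < 5L))
    stop("every group needs at least 5 values (smallest has ",
         min(ns), ")", call. = FALSE)
  if (is.null(names(measurements)))
    names(measurements) <- paste0("group", seq_along(measurements))
  if (is.null(control)) control <- names(measurements)[1]
  if (!control %in% names(measurements))
    stop("control group '", control, "' not found", call. = FALSE)

  values <- unlist(measurements, use.names = FALSE)
  groups <- factor(rep(names(measurements), ns),
                   levels = names(measurements))

  norm_p <- vapply(measurements, function(g) {
    if (length(g) < 8L || stats::sd(g) == 0) return(0)
    dagostino_pearson_test(g)$p.value
  }, numeric(1))
  summary_df <- data.frame(group = names(measurements), n = ns,
                           mean = vapply(measurements, mean, numeric(1)),
                           sd = vapply(measurements, stats::sd,
                                       numeric(1)),
                           normality_p = norm_p, row.names = NULL)

  if (stats::sd(values) == 0) {
    # fully degenerate family: identical constants everywhere
    pairwise <- data.frame(group = setdiff(names(measurements), control),
                           estimate = 0, statistic = 0,
                           p_unadjusted = 1, p_adjusted = 1, tier = "ns")
    return(structure(list(summary = summary_df, method = "degenerate",
                          statistic = 0, p.value = 1,
                          pairwise = pairwise, control = control),
                     class = "group_comparison"))
  }

  parametric <- all(norm_p > alpha)
  if (parametric) {
    fit <- stats::aov(values ~ groups)
    an <- summary(fit)[[1]]
    tuk <- stats::TukeyHSD(fit)$groups
    # rows comparing each non-control group to control
    others <- setdiff(names(measurements), control)
    rn <- rownames(tuk)
    pick <- function(g) {
      i <- match(paste(g, control, sep = "-"), rn)
      sgn <- 1
      if (is.na(i)) {
        i <- match(paste(control, g, sep = "-"), rn)
        sgn <- -1
      }
      c(est = sgn * tuk[i, "diff"], p = tuk[i, "p adj"])
    }
    pc <- vapply(others, pick, numeric(2))
    pairwise <- data.frame(group = others, estimate = pc["est", ],
                           statistic = NA_real_, p_unadjusted = NA_real_,
                           p_adjusted = pc["p", ],
                           tier = significance_tier(pc["p", ]),
                           row.names = NULL)
    method <- "one-way ANOVA + Tukey HSD"
    statistic <- an[["F value"]][1]
    p_omni <- an[["Pr(>F)"]][1]
  } else {
    kw <- stats::kruskal.test(values, groups)
    pairwise <- dunn_vs_control(values, groups, control)
    method <- "Kruskal-Wallis + Dunn vs control"
    statistic <- unname(kw$statistic)
    p_omni <- kw$p.value
  }

  structure(list(summary = summary_df, method = method,
                 statistic = statistic, p.value = p_omni,
                 pairwise = pairwise, control = control),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (", x$method, ")\n", sep = "")
  cat(sprintf("  omnibus statistic %.4g, p = %.4g\n",
              x$statistic, x$p.value))
  print(x$summary, row.names = FALSE)
  cat("Pairwise vs", x$control, ":\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
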