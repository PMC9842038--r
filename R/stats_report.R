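#' Welch two-sample t test as a group comparison
#'
#' Unpaired t test with Welch's correction (Welch--Satterthwaite degrees of
#' freedom), two-sided. Welch is the default for all two-group comparisons in
#' this package: it does not assume equal variances, which imaging-derived
#' measures rarely satisfy.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param labels group labels for reporting.
#' @param alpha nominal significance level carried into the result.
#' @return a \linkS4class{GroupComparisonResult}
#' @export
welchT <- function(a, b, labels = c("a", "b"), alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample must contain at least 2 values")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  new("GroupComparisonResult", testName = "welch_t",
      groups = data.frame(label = labels, n = c(length(a), length(b))),
      statistic = c(t = unname(tt$statistic)),
      pValue = c(t = unname(tt$p.value)),
      posthoc = NULL, alpha = alpha)
}

## Dunnett many-to-one comparisons against a control group, adjusted through
## the multivariate-t dependency structure of the simultaneous statistics
## (mvtnorm::pmvt; the quasi-Monte-Carlo integration is run under a fixed,
## recorded seed so reruns are identical).
.dunnett <- function(values, groups, control, alpha = 0.05, mcSeed = 1L) {
  groups <- as.factor(groups)
  if (!control %in% levels(groups))
    stop("dunnett post hoc requires a control label present in the groups")
  lev <- levels(groups)
  others <- setdiff(lev, control)
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  N <- length(values); k <- length(lev)
  df <- N - k
  s2 <- sum(tapply(values, groups,
                   function(x) sum((x - mean(x))^2))) / df
  lam <- sqrt(n[others] / (n[others] + n[control]))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  res <- data.frame(pair = paste(others, "-", control),
                    estimate = NA_real_, statistic = NA_real_,
                    p_unadjusted = NA_real_, p_adjusted = NA_real_)
  for (i in seq_along(others)) {
    est <- m[others[i]] - m[control]
    se <- sqrt(s2 * (1 / n[others[i]] + 1 / n[control]))
    tstat <- est / se
    punadj <- 2 * stats::pt(-abs(tstat), df)
    set.seed(mcSeed)
    padj <- 1 - mvtnorm::pmvt(lower = rep(-abs(tstat), length(others)),
                              upper = rep(abs(tstat), length(others)),
                              df = as.integer(df), corr = corr)[1]
    res$estimate[i] <- est
    res$statistic[i] <- tstat
    res$p_unadjusted[i] <- punadj
    res$p_adjusted[i] <- min(1, max(padj, punadj))
  }
  res
}

## anova() warns on perfect fits; degenerate F statistics are handled
## explicitly downstream, so that warning carries no information here.
.quietAnova <- function(fit) {
  withCallingHandlers(stats::anova(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.tukey <- function(values, groups) {
  fit <- stats::aov(values ~ g, data = data.frame(values = values,
                                                  g = as.factor(groups)))
  th <- stats::TukeyHSD(fit)$g
  data.frame(pair = rownames(th), estimate = th[, "diff"],
             p_adjusted = th[, "p adj"], row.names = NULL)
}

#' One-way ANOVA with optional Dunnett or Tukey post hoc comparisons
#'
#' Ordinary (equal-variance) one-way analysis of variance; with two groups
#' the F statistic equals the square of the pooled t statistic. Dunnett's
#' many-to-one adjustment is computed from the multivariate-t distribution of
#' the simultaneous statistics; Tukey's HSD covers all pairs.
#'
#' @param values numeric response.
#' @param groups group labels, one per value; every group needs n >= 2.
#' @param posthoc "none", "dunnett" or "tukey".
#' @param control control-group label (required for Dunnett).
#' @param alpha nominal significance level carried into the result.
#' @param mcSeed seed for the multivariate-t integration (recorded).
#' @return a \linkS4class{GroupComparisonResult}
#' @export
oneWayAnova <- function(values, groups, posthoc = c("none", "dunnett",
                                                    "tukey"),
                        control = NULL, alpha = 0.05, mcSeed = 1L) {
  posthoc <- match.arg(posthoc)
  groups <- as.factor(groups)
  n <- tapply(values, groups, length)
  if (length(n) < 2L) stop("at least two groups are required")
  if (any(n < 2L)) stop("every group needs at least 2 values")
  an <- .quietAnova(stats::lm(values ~ g,
                              data = data.frame(values = values, g = groups)))
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (an[["Sum Sq"]][1] < 1e-12 * max(an[["Sum Sq"]][2], 1)) {
    Fv <- 0; pv <- 1   # identical group means (possibly with 0 residual MS)
  }
  ph <- switch(posthoc,
    none = NULL,
    dunnett = {
      if (is.null(control)) stop("dunnett post hoc requires a control label")
      .dunnett(values, groups, control, alpha = alpha, mcSeed = mcSeed)
    },
    tukey = .tukey(values, groups))
  new("GroupComparisonResult", testName = "one_way_anova",
      groups = data.frame(label = levels(groups), n = as.integer(n)),
      statistic = c(F = Fv), pValue = c(F = pv), posthoc = ph, alpha = alpha)
}

#' Two-way ANOVA (balanced full factorial) with post hoc on cell means
#'
#' Standard two-factor decomposition into main effects and interaction.
#' Only balanced designs with n >= 2 per cell are accepted; unbalanced data
#' are rejected loudly rather than silently re-weighted. Post hoc comparisons
#' run on the factor-combination cell means.
#'
#' @param values numeric response.
#' @param factorA,factorB factor labels (e.g. sex and medium), one per value.
#' @param posthoc "none", "dunnett" or "tukey".
#' @param control control cell label ("A.B" form) for Dunnett.
#' @param alpha nominal significance level.
#' @param mcSeed seed for the Dunnett multivariate-t integration.
#' @return a \linkS4class{GroupComparisonResult} whose statistic and pValue
#'   are named vectors over (factor_a, factor_b, interaction).
#' @export
twoWayAnova <- function(values, factorA, factorB,
                        posthoc = c("none", "dunnett", "tukey"),
                        control = NULL, alpha = 0.05, mcSeed = 1L) {
  posthoc <- match.arg(posthoc)
  A <- as.factor(factorA); B <- as.factor(factorB)
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("a full factorial design needs at least two levels per factor")
  tab <- table(A, B)
  if (any(tab == 0)) stop("empty cells: a full factorial design is required")
  if (length(unique(as.vector(tab))) != 1L)
    stop("unbalanced design: equal cell sizes are required")
  if (any(tab < 2L)) stop("every cell needs at least 2 values")
  dat <- data.frame(y = values, A = A, B = B)
  an <- .quietAnova(stats::lm(y ~ A * B, data = dat))
  ss <- an[["Sum Sq"]]; Fv <- an[["F value"]][1:3]; pv <- an[["Pr(>F)"]][1:3]
  degenerate <- ss[1:3] < 1e-12 * max(ss[4], 1)
  Fv[degenerate] <- 0; pv[degenerate] <- 1
  names(Fv) <- names(pv) <- c("factor_a", "factor_b", "interaction")
  cells <- interaction(A, B, sep = ".")
  ph <- switch(posthoc,
    none = NULL,
    dunnett = {
      if (is.null(control))
        stop("dunnett post hoc requires a control cell label ('A.B')")
      .dunnett(values, cells, control, alpha = alpha, mcSeed = mcSeed)
    },
    tukey = .tukey(values, cells))
  new("GroupComparisonResult", testName = "two_way_anova",
      groups = data.frame(label = levels(cells),
                          n = as.integer(table(cells))),
      statistic = Fv, pValue = pv, posthoc = ph, alpha = alpha)
}
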