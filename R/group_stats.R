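#' Compare a parameter across glioma subtypes with a normality-gated tree
#'
#' Implements the decision tree used for three-group comparisons: the
#' Shapiro-Wilk test is applied to each group; if every group is
#' consistent with normality (all p > `alpha`), a one-way ANOVA is run and,
#' when significant, followed by Tukey's honestly-significant-difference
#' test. Otherwise the Kruskal-Wallis test is used, followed when
#' significant by Dunn's test with Bonferroni correction over the pairs.
#' A group on which Shapiro-Wilk is inapplicable (e.g. constant values) is
#' flagged (`NA` normality p) and routes the comparison to the
#' Kruskal-Wallis branch.
#'
#' @param groups named list of numeric vectors, one per group (>= 3
#'   groups, >= 3 observations each).
#' @param alpha significance level for both the normality gate and the
#'   omnibus test (default 0.05).
#' @param parameter label recorded in the result.
#' @param test `"auto"` (default: the normality-gated tree) or a forced
#'   branch, `"anova"` / `"kruskal"`.
#' @return A [GroupComparison-class].
#' @export
compareGroups <- function(groups, alpha = 0.05, parameter = "parameter",
                          test = c("auto", "anova", "kruskal")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 3L)
    stop("need a list of >= 3 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  ns <- lengths(groups)
  if (any(ns < 3L))
    stop("every group needs >= 3 observations (got ",
         paste(ns, collapse = ", "), ")")
  normP <- vapply(groups, function(g) {
    tryCatch(stats::shapiro.test(g)$p.value, error = function(e) NA_real_)
  }, numeric(1L))

  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  useAnova <- if (test == "auto") all(!is.na(normP)) && all(normP > alpha)
              else test == "anova"

  if (useAnova) {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1L]]
    stat <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
    posthoc <- .emptyPosthoc()
    if (is.finite(p) && p <= alpha) {
      tk <- stats::TukeyHSD(fit)$g
      posthoc <- data.frame(pair = rownames(tk), statistic = tk[, "diff"],
                            p_adj = tk[, "p adj"], method = "Tukey HSD",
                            row.names = NULL)
    }
    test <- "anova"
  } else {
    kw <- stats::kruskal.test(x, g)
    stat <- unname(kw$statistic)
    p <- kw$p.value
    posthoc <- .emptyPosthoc()
    if (is.finite(p) && p <= alpha) posthoc <- dunnTest(x, g, adjust = "bonferroni")
    test <- "kruskal"
  }
  if (is.na(p)) stat <- NA_real_
  new("GroupComparison", parameter = parameter, groups = groups,
      normalityP = normP, test = test, statistic = stat, p = p,
      posthoc = posthoc, alpha = alpha)
}

.emptyPosthoc <- function() {
  data.frame(pair = character(), statistic = numeric(), p_adj = numeric(),
             method = character())
}

#' Dunn's post hoc test with tie correction
#'
#' Pairwise rank comparisons following a significant Kruskal-Wallis test.
#' For groups i, j the statistic is
#' \deqn{z_{ij} = \frac{\bar r_i - \bar r_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12(N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}},}
#' with \eqn{\bar r} mean pooled ranks, \eqn{N} the total sample size and
#' \eqn{t} the tie multiplicities. Two-sided p-values are multiplied by the
#' number of pairs (Bonferroni) and clamped at 1.
#'
#' @param x numeric vector of pooled observations.
#' @param g factor of group membership.
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return data.frame: pair, statistic (z), p_adj, method.
#' @export
dunnTest <- function(x, g, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  g <- droplevels(as.factor(g))
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2base <- N * (N + 1) / 12 - tieCorr
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  z <- p <- numeric(m)
  lab <- character(m)
  for (k in seq_len(m)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(sigma2base * (1 / n[[i]] + 1 / n[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
    lab[k] <- paste(i, j, sep = "-")
  }
  if (adjust == "bonferroni") p <- pmin(1, m * p)
  data.frame(pair = lab, statistic = z, p_adj = p,
             method = if (adjust == "bonferroni") "Dunn-Bonferroni" else "Dunn")
}
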