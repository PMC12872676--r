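#' Multiple regression of global GCIPL thickness on demographics
#'
#' Ordinary least squares of grid-mean GCIPL thickness on age (years), axial
#' length (mm) and sex (male = 0, female = 1), with intercept. A
#' rank-deficient design raises an error naming the aliased terms.
#'
#' @param data data.frame with \code{thickness}, \code{age},
#'   \code{axial_length}, \code{sex}.
#' @param formula model formula (default
#'   \code{thickness ~ age + axial_length + sex}).
#' @return list of class \code{wgLinearModel}: \code{coefficients}
#'   (data.frame term/estimate/se/p), \code{adjR2}, \code{rmse}, \code{n},
#'   \code{fit} (the \code{lm} object).
#' @export
globalRegression <- function(data,
                             formula = thickness ~ age + axial_length + sex) {
  fit <- stats::lm(formula, data = data)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    bad <- names(which(is.na(stats::coef(fit))))
    stop("collinear design: aliased term(s) ", paste(bad, collapse = ", "))
  }
  if (stats::df.residual(fit) < 1)
    stop("more terms than observations")
  s <- summary(fit)
  structure(list(
    coefficients = data.frame(
      term = rownames(s$coefficients),
      estimate = s$coefficients[, 1], se = s$coefficients[, 2],
      p = s$coefficients[, 4], row.names = NULL),
    adjR2 = s$adj.r.squared,
    rmse = s$sigma,
    n = length(stats::fitted(fit)),
    fit = fit), class = "wgLinearModel")
}

#' @export
print.wgLinearModel <- function(x, ...) {
  cat("Linear model (n =", x$n, "): adj R2 =",
      sprintf("%.3f", x$adjR2), ", RMSE =", sprintf("%.2f", x$rmse), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Percentage change between two estimates of a coefficient
#'
#' The elimination criterion: 100 |beta_full - beta_reduced| / |beta_full|.
#'
#' @param full,reduced the coefficient in the full / reduced model.
#' @return percentage difference.
#' @examples
#' coefficientChangePct(-0.053, -0.050)  # 5.66
#' @export
coefficientChangePct <- function(full, reduced) {
  100 * abs(full - reduced) / abs(full)
}

#' Backward elimination with the 10 percent coefficient-change rule
#'
#' To mitigate over-fitting, the least significant main effect is removed
#' and the model refitted; if any remaining coefficient changes by more than
#' \code{threshold} percent the removed effect is deemed sufficiently
#' impactful, restored, and the procedure stops. Otherwise the reduced model
#' is adopted and the step repeats while at least two candidate terms remain.
#' Rerunning the procedure on its own retained model changes nothing.
#'
#' @param formula full model formula.
#' @param data model data.
#' @param threshold percentage-change threshold (default 10).
#' @return list of class \code{wgElimination}: \code{retained} (term names),
#'   \code{eliminated}, \code{steps} (per attempt: removed term, coefficient
#'   tables, percentage differences, decision), \code{finalFit} (an
#'   \code{lm}).
#' @export
backwardElimination <- function(formula, data, threshold = 10) {
  terms0 <- attr(stats::terms(formula, data = data), "term.labels")
  if (length(terms0) < 2) stop("need at least 2 candidate terms")
  response <- all.vars(formula)[1]
  current <- terms0
  eliminated <- character()
  steps <- list()
  repeat {
    f <- stats::reformulate(current, response = response)
    fit <- stats::lm(f, data = data)
    if (length(current) < 2) break
    p <- summary(fit)$coefficients[-1, 4]
    drop <- names(which.max(p))
    reducedTerms <- setdiff(current, drop)
    rfit <- stats::lm(stats::reformulate(reducedTerms, response = response),
                      data = data)
    shared <- intersect(names(stats::coef(fit)), names(stats::coef(rfit)))
    shared <- setdiff(shared, "(Intercept)")
    pct <- coefficientChangePct(stats::coef(fit)[shared],
                                stats::coef(rfit)[shared])
    keepIt <- any(pct > threshold)
    steps[[length(steps) + 1L]] <- list(
      removed = drop,
      fullCoefficients = stats::coef(fit),
      reducedCoefficients = stats::coef(rfit),
      pctChange = pct,
      decision = if (keepIt) "restored" else "eliminated")
    if (keepIt) break
    current <- reducedTerms
    eliminated <- c(eliminated, drop)
  }
  structure(list(retained = current, eliminated = eliminated, steps = steps,
                 finalFit = stats::lm(
                   stats::reformulate(current, response = response),
                   data = data),
                 threshold = threshold),
            class = "wgElimination")
}

#' @export
print.wgElimination <- function(x, ...) {
  cat("Backward elimination (", x$threshold, "% rule): retained ",
      paste(x$retained, collapse = " + "), "\n", sep = "")
  for (s in x$steps)
    cat(sprintf("  tried removing %s -> max coefficient change %.2f%% (%s)\n",
                s$removed, max(s$pctChange), s$decision))
  invisible(x)
}

#' Repeatability coefficient between paired grid measurements
#'
#' Agreement between GCIPL grids corrected with measured versus
#' refraction-predicted axial lengths:
#' \deqn{C_R = 1.96 \sqrt{\sum |m_i - c_i| / n}}
#' (the mean absolute difference under the root, as published). The
#' conventional Bland-Altman form 1.96 x SD of the differences is available
#' as \code{convention = "classic"}.
#'
#' @param measured,calculated paired values (um) over the same grid squares.
#' @param convention "published" or "classic".
#' @return list of class \code{wgRepeatability}: \code{cR}, \code{n},
#'   \code{convention}.
#' @export
repeatabilityCoefficient <- function(measured, calculated,
                                     convention = c("published", "classic")) {
  convention <- match.arg(convention)
  stopifnot(length(measured) == length(calculated))
  ok <- is.finite(measured) & is.finite(calculated)
  n <- sum(ok)
  if (n < 1) stop("no overlapping defined squares")
  d <- measured[ok] - calculated[ok]
  cR <- if (convention == "published") 1.96 * sqrt(mean(abs(d)))
  else 1.96 * stats::sd(d)
  structure(list(cR = cR, n = n, convention = convention),
            class = "wgRepeatability")
}

#' @export
print.wgRepeatability <- function(x, ...) {
  cat(sprintf("Repeatability coefficient (%s): C_R = %.3f over n = %d squares\n",
              x$convention, x$cR, x$n))
  invisible(x)
}

#' Sliding decade-window means
#'
#' Maintaining decade-sized windows, one year is sequentially added to the
#' start of each age bracket (offset 0: 20-<30 ... 70+; offset 1: 21-<31 ...
#' 71+; and so on up to offset 9). Values falling within each window are
#' averaged per cluster and paired with the window's mean age; all offsets
#' are concatenated. Empty windows are dropped with a message.
#'
#' @param data data.frame with \code{value}, \code{age} and optionally
#'   \code{cluster} (absent = one pooled series).
#' @param width window width in years (default 10).
#' @param startAge first lower edge at offset 0 (default 20).
#' @param nWindows windows per offset (default 6; the last is open-ended).
#' @param offsets integer offsets to apply (default 0:9).
#' @return data.frame: \code{offset}, \code{windowStart}, \code{cluster},
#'   \code{meanAge}, \code{meanValue}, \code{n}.
#' @export
slidingWindow <- function(data, width = 10, startAge = 20, nWindows = 6L,
                          offsets = 0:9) {
  stopifnot(all(c("value", "age") %in% names(data)))
  if (is.null(data$cluster)) data$cluster <- 1L
  if (diff(range(data$age)) < width)
    stop("cohort must span at least two windows")
  out <- list()
  dropped <- 0L
  for (o in offsets) {
    lowers <- startAge + o + width * (0:(nWindows - 1L))
    for (w in seq_along(lowers)) {
      lo <- lowers[w]
      hi <- if (w == nWindows) Inf else lowers[w] + width
      inWin <- data$age >= lo & data$age < hi
      if (!any(inWin)) { dropped <- dropped + 1L; next }
      sub <- data[inWin, ]
      agg <- stats::aggregate(sub$value, by = list(cluster = sub$cluster),
                              FUN = mean)
      out[[length(out) + 1L]] <- data.frame(
        offset = o, windowStart = lo, cluster = agg$cluster,
        meanAge = rep(mean(sub$age), nrow(agg)), meanValue = agg$x,
        n = rep(sum(inWin), nrow(agg)))
    }
  }
  if (dropped > 0) message(dropped, " empty window(s) dropped")
  do.call(rbind, out)
}

#' Linear versus quadratic model comparison
#'
#' Nested OLS fits of degree 1 and 2 compared with the extra sum-of-squares
#' F test, F = ((RSS1 - RSS2)/1) / (RSS2/(n-3)) with p from F(1, n-3), and
#' adjusted R-squared for both models.
#'
#' @param x,y predictor (age) and response.
#' @return list of class \code{wgModelComparison}: \code{fStatistic},
#'   \code{pValue}, \code{adjR2Simple}, \code{adjR2Complex}, \code{n}.
#' @export
compareLinearQuadratic <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0) stop("degenerate predictor: no spread in x")
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + I(x^2))
  rss1 <- sum(stats::residuals(f1)^2)
  rss2 <- sum(stats::residuals(f2)^2)
  fStat <- ((rss1 - rss2) / 1) / (rss2 / (n - 3))
  structure(list(
    fStatistic = fStat,
    pValue = stats::pf(fStat, 1, n - 3, lower.tail = FALSE),
    adjR2Simple = summary(f1)$adj.r.squared,
    adjR2Complex = summary(f2)$adj.r.squared,
    n = n), class = "wgModelComparison")
}

#' @export
print.wgModelComparison <- function(x, ...) {
  cat(sprintf(
    "Linear vs quadratic: F = %.3f, p = %.4g; adj R2 %.3f -> %.3f (n = %d)\n",
    x$fStatistic, x$pValue, x$adjR2Simple, x$adjR2Complex, x$n))
  invisible(x)
}

#' Mixed-effects ageing model across clusters
#'
#' GCIPL thickness averaged per cluster is modelled with fixed effects age,
#' cluster identity and their interaction, and a random intercept per
#' subject eye (accounting for the multiple clustered values each eye
#' contributes). With \code{logScale}, the response is log10 thickness
#' (percentage change per year). Estimated marginal means, which hold the
#' random effect constant across participants, are computed over the age
#' bracket grid, and per-cluster slopes via marginal trends.
#'
#' @param data data.frame with \code{value}, \code{age}, \code{cluster},
#'   \code{eye}.
#' @param logScale model log10(value) (values must be positive; offending
#'   rows are listed otherwise).
#' @param bracketAges age values for the marginal-mean grid (default decade
#'   bracket midpoints 25..75).
#' @return list of class \code{wgMixedFit}: \code{model} (lmerMod),
#'   \code{slopes} (per-cluster trend, SE, CI), \code{emm} (estimated
#'   marginal means per cluster x age), \code{logScale}.
#' @export
mixedEffectsByCluster <- function(data, logScale = FALSE,
                                  bracketAges = seq(25, 75, by = 10)) {
  stopifnot(all(c("value", "age", "cluster", "eye") %in% names(data)))
  if (length(unique(data$cluster)) < 2) stop("need at least 2 clusters")
  if (length(unique(data$eye)) < 2) stop("need at least 2 eyes")
  d <- data
  if (logScale) {
    bad <- which(!(d$value > 0))
    if (length(bad))
      stop("log scale requires positive values; offending rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    d$resp <- log10(d$value)
  } else d$resp <- d$value
  d$cluster <- factor(d$cluster)
  d$eye <- factor(d$eye)
  model <- lmerTest::lmer(resp ~ age * cluster + (1 | eye), data = d)
  tr <- emmeans::emtrends(model, ~cluster, var = "age",
                          lmer.df = "satterthwaite")
  slopes <- as.data.frame(tr)
  names(slopes)[2] <- "slope"
  emm <- as.data.frame(emmeans::emmeans(
    model, ~cluster * age, at = list(age = bracketAges),
    lmer.df = "satterthwaite"))
  structure(list(model = model, slopes = slopes, emm = emm,
                 logScale = logScale), class = "wgMixedFit")
}

#' @export
print.wgMixedFit <- function(x, ...) {
  cat("Mixed-effects ageing model",
      if (x$logScale) "(log10 scale)" else "(um scale)",
      "- per-cluster slopes:\n")
  print(x$slopes[, c("cluster", "slope", "SE")], digits = 3)
  invisible(x)
}

#' Per-cluster linear ageing fits
#'
#' OLS of (optionally log10) thickness on age for each cluster, on pooled
#' bracket data or estimated marginal means; reports slope, intercept,
#' R-squared and RMSE (root of RSS over residual df).
#'
#' @param data data.frame with \code{value}, \code{age}, \code{cluster}.
#' @param logScale fit log10(value).
#' @return data.frame of class \code{wgRegressionFits}: \code{cluster},
#'   \code{slope}, \code{intercept}, \code{r2}, \code{rmse}, \code{n}.
#' @export
perClusterLinearFit <- function(data, logScale = FALSE) {
  stopifnot(all(c("value", "age", "cluster") %in% names(data)))
  res <- lapply(split(data, data$cluster), function(d) {
    if (nrow(d) < 3) stop("need >= 3 age points per cluster (cluster ",
                          d$cluster[1], ")")
    y <- if (logScale) log10(d$value) else d$value
    f <- stats::lm(y ~ age, data = d)
    r2 <- summary(f)$r.squared
    data.frame(cluster = d$cluster[1],
               slope = unname(stats::coef(f)[2]),
               intercept = unname(stats::coef(f)[1]),
               r2 = if (is.finite(r2)) r2 else 0,  # constant response
               rmse = summary(f)$sigma,
               n = nrow(d))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("wgRegressionFits", "data.frame")
  out
}

#' Tests of a shared ageing slope across clusters
#'
#' (a) Global test of a common age slope: likelihood ratio between the mixed
#' models with and without the age x cluster interaction (ML fits), and the
#' extra sum-of-squares F test on the pooled OLS analogue. (b) Post-hoc
#' pairwise slope contrasts between clusters with Tukey family-wise
#' adjustment (marginal trends of the interaction model). (c) Optional
#' grouped-equality F tests for user-specified cluster groupings.
#'
#' @param data data.frame with \code{value}, \code{age}, \code{cluster},
#'   \code{eye}.
#' @param groupings optional list of integer vectors of cluster ids; each is
#'   tested for slope equality within the group.
#' @param logScale analyse log10(value).
#' @return list of class \code{wgSharedSlopeTests}: \code{lr} (statistic,
#'   df, p), \code{olsF} (F, df, p), \code{tukey} (contrast data.frame),
#'   \code{groupTests} (data.frame per grouping).
#' @export
sharedSlopeTests <- function(data, groupings = NULL, logScale = FALSE) {
  d <- data
  if (logScale) {
    stopifnot(all(d$value > 0))
    d$resp <- log10(d$value)
  } else d$resp <- d$value
  known <- unique(d$cluster)
  if (!is.null(groupings)) {
    unknown <- setdiff(unlist(groupings), known)
    if (length(unknown))
      stop("grouping references unknown cluster(s): ",
           paste(unknown, collapse = ", "))
  }
  d$cluster <- factor(d$cluster)
  d$eye <- factor(d$eye)
  mFull <- lme4::lmer(resp ~ age * cluster + (1 | eye), data = d, REML = FALSE)
  mRed <- lme4::lmer(resp ~ age + cluster + (1 | eye), data = d, REML = FALSE)
  a <- stats::anova(mRed, mFull)
  lr <- list(statistic = a$Chisq[2], df = a$Df[2],
             p = a$`Pr(>Chisq)`[2])
  f1 <- stats::lm(resp ~ age * cluster, data = d)
  f0 <- stats::lm(resp ~ age + cluster, data = d)
  ao <- stats::anova(f0, f1)
  olsF <- list(statistic = ao$F[2], df1 = ao$Df[2], df2 = ao$Res.Df[2],
               p = ao$`Pr(>F)`[2])
  trFull <- lmerTest::lmer(resp ~ age * cluster + (1 | eye), data = d)
  tk <- emmeans::emtrends(trFull, pairwise ~ cluster, var = "age",
                          adjust = "tukey", lmer.df = "satterthwaite")
  tukey <- as.data.frame(tk$contrasts)
  groupTests <- NULL
  if (!is.null(groupings)) {
    groupTests <- do.call(rbind, lapply(groupings, function(g) {
      sub <- d[d$cluster %in% as.character(g), ]
      sub$cluster <- droplevels(sub$cluster)
      if (nlevels(sub$cluster) < 2)
        return(data.frame(group = paste(g, collapse = ","),
                          f = NA_real_, p = NA_real_))
      g1 <- stats::lm(resp ~ age * cluster, data = sub)
      g0 <- stats::lm(resp ~ age + cluster, data = sub)
      av <- stats::anova(g0, g1)
      data.frame(group = paste(g, collapse = ","),
                 f = av$F[2], p = av$`Pr(>F)`[2])
    }))
  }
  structure(list(lr = lr, olsF = olsF, tukey = tukey,
                 groupTests = groupTests, logScale = logScale),
            class = "wgSharedSlopeTests")
}

#' @export
print.wgSharedSlopeTests <- function(x, ...) {
  cat("Shared-slope tests",
      if (x$logScale) "(log10 scale)\n" else "(um scale)\n")
  cat(sprintf("  LR = %.2f (df %d), p = %.3g\n",
              x$lr$statistic, x$lr$df, x$lr$p))
  cat(sprintf("  extra-SS F = %.2f (%d, %d), p = %.3g\n",
              x$olsF$statistic, x$olsF$df1, x$olsF$df2, x$olsF$p))
  if (!is.null(x$groupTests)) {
    cat("  grouped-equality tests:\n")
    print(x$groupTests, digits = 3)
  }
  invisible(x)
}

#' Cluster groups sharing a slope, from Tukey contrasts
#'
#' Greedy grouping of thickness-ordered clusters: walk the ordered clusters
#' and extend the current group while every pairwise contrast inside the
#' extended group is non-significant at \code{alpha}.
#'
#' @param tukey the \code{tukey} data.frame from
#'   \code{\link{sharedSlopeTests}}.
#' @param clusters cluster ids in thickness order.
#' @param alpha significance level (default 0.05).
#' @return list of integer vectors (the groups, in order).
#' @export
slopeGroups <- function(tukey, clusters, alpha = 0.05) {
  ids <- regmatches(as.character(tukey$contrast),
                    gregexpr("[0-9]+", as.character(tukey$contrast)))
  pairIds <- t(vapply(ids, function(v) as.integer(v[1:2]), integer(2)))
  sig <- function(a, b) {
    hit <- (pairIds[, 1] == a & pairIds[, 2] == b) |
      (pairIds[, 1] == b & pairIds[, 2] == a)
    any(tukey$p.value[hit] < alpha)
  }
  groups <- list()
  cur <- clusters[1]
  for (c in clusters[-1]) {
    if (any(vapply(cur, function(a) sig(a, c), TRUE))) {
      groups[[length(groups) + 1L]] <- cur
      cur <- c
    } else cur <- c(cur, c)
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}
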