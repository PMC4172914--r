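#' Fit the random variance model hyperparameters
#'
#' The random variance model (RVM) assumes the per-feature residual
#' variances share an inverse-gamma prior: precisions `1/sigma^2 ~
#' Gamma(shape a, scale b)`. Marginally over that prior, an observed
#' residual variance `s^2` on `m` degrees of freedom satisfies
#' `s^2 * a * b ~ F(m, 2a)`, and `(a, b)` are estimated by maximizing the
#' corresponding likelihood across features. The fit tolerates per-feature
#' degrees of freedom (features with missing wells contribute fewer df).
#'
#' Optimization is over `(log a, log b)` (unconstrained) with Nelder-Mead
#' from three documented starts: method-of-moments-style values
#' `a0 in {1.5, 3, 10}` with `b0 = 1/(mean(s^2) * (a0 - 1))`, which match
#' the prior's mean variance `1/(b (a - 1))` to the sample mean.
#'
#' @param variances per-feature residual variances `s^2` (>= 10 positive
#'   values required). Zero variances are excluded from the fit.
#' @param df residual degrees of freedom, scalar or per-feature (>= 1).
#' @return An [RvmFit-class] with slots `a`, `b`, `converged`, `loglik`,
#'   `nFeaturesUsed`.
#' @references Wright, G.W. and Simon, R.M. (2003) A random variance model
#'   for detection of differential gene expression in small microarray
#'   experiments. Bioinformatics 19, 2448-2455.
#' @examples
#' set.seed(1)
#' sigma2 <- 1 / rgamma(2000, shape = 2, scale = 1)
#' s2 <- sigma2 * rchisq(2000, df = 4) / 4
#' fitRvm(s2, df = 4)
#' @export
fitRvm <- function(variances, df) {
  variances <- as.numeric(variances)
  df <- rep_len(as.numeric(df), length(variances))
  if (any(df < 1, na.rm = TRUE)) stop("df must be >= 1")
  ok <- is.finite(variances) & variances > 0 & is.finite(df)
  if (sum(ok) < 10L)
    stop("need >= 10 features with positive residual variance to fit the ",
         "variance prior (got ", sum(ok), ")")
  if (all(variances[ok] == 0))
    stop("all residual variances are zero; variance prior is degenerate")
  s2 <- variances[ok]
  m <- df[ok]

  negll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(log(a * b) + stats::df(a * b * s2, m, 2 * a, log = TRUE))
  }
  starts <- lapply(c(1.5, 3, 10), function(a0)
    c(log(a0), log(1 / (mean(s2) * (a0 - 1)))))
  fits <- lapply(starts, function(p0)
    tryCatch(stats::optim(p0, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    return(new("RvmFit", a = NA_real_, b = NA_real_, converged = FALSE,
               loglik = -Inf, nFeaturesUsed = sum(ok)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  new("RvmFit",
      a = exp(best$par[1]), b = exp(best$par[2]),
      converged = best$convergence == 0L,
      loglik = -best$value,
      nFeaturesUsed = as.integer(sum(ok)))
}

#' Log-likelihood of RVM hyperparameters
#' @param fit an [RvmFit-class] or a list/vector with elements `a`, `b`.
#' @param variances,df as in [fitRvm()].
#' @return scalar log-likelihood of `(a, b)` under the scaled-F marginal.
#' @export
rvmLoglik <- function(fit, variances, df) {
  a <- if (is(fit, "RvmFit")) fit@a else fit[["a"]]
  b <- if (is(fit, "RvmFit")) fit@b else fit[["b"]]
  df <- rep_len(as.numeric(df), length(variances))
  ok <- is.finite(variances) & variances > 0
  sum(log(a * b) + stats::df(a * b * variances[ok], df[ok], 2 * a,
                             log = TRUE))
}

setMethod("show", "RvmFit", function(object) {
  cat("RvmFit: a =", signif(object@a, 4), ", b =", signif(object@b, 4),
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  loglik", signif(object@loglik, 6), "on", object@nFeaturesUsed,
      "features; extra df from prior: 2a =", signif(2 * object@a, 4), "\n")
})

#' RVM-moderated two-group t-test on delta-CT values
#'
#' For each feature, the pooled residual variance `s^2` on
#' `m = n1 + n2 - 2` df is shrunk toward the fitted inverse-gamma prior:
#' `s_tilde^2 = (m s^2 + 2/b) / (m + 2a)`, and the moderated statistic
#' `t = (mean_ref - mean_cmp) / sqrt(s_tilde^2 (1/n1 + 1/n2))` is referred
#' to a t distribution on `m + 2a` degrees of freedom (two-sided). Sharing
#' the prior across features is what raises the effective degrees of
#' freedom beyond the within-feature `m` — the point of the RVM at n = 3
#' per group. The test runs on the delta-CT scale, where replicate values
#' are approximately normal; with `reference` first, positive `t` tracks
#' fold changes above 1 (higher expression in the comparison group lowers
#' its delta-CT).
#'
#' If `fit` did not converge the function falls back to the ordinary
#' pooled-variance t-test (df `m`) with a warning.
#'
#' @param x a [DeltaCtPanel-class].
#' @param fit an [RvmFit-class] from [fitRvm()], or `NULL` to fit on the
#'   pooled residual variances of `x` itself.
#' @param reference,comparison the two group labels.
#' @return data.frame with columns `mirna_id`, `t`, `df`, `p_value`, plus
#'   the per-feature `s2` (pooled) and `s2_shrunk`.
#' @examples
#' sim <- simulateCtPanel(panelConfig(seed = 11))
#' dct <- deltaCt(sim$panel)
#' head(rvmTest(dct, reference = "newborn", comparison = "adult"))
#' @export
rvmTest <- function(x, fit = NULL, reference, comparison) {
  stopifnot(is(x, "DeltaCtPanel"))
  g <- as.character(groupLabels(x))
  for (nm in c(reference, comparison))
    if (!nm %in% g) stop("unknown group: ", nm)
  dct <- deltaCtValues(x)
  A <- dct[, g == reference, drop = FALSE]
  B <- dct[, g == comparison, drop = FALSE]
  n1 <- rowSums(!is.na(A)); n2 <- rowSums(!is.na(B))
  if (any(n1 < 2 | n2 < 2))
    stop("every feature needs >= 2 detected samples per group; ",
         "run filterDetected() first")
  m1 <- rowMeans(A, na.rm = TRUE); m2 <- rowMeans(B, na.rm = TRUE)
  v1 <- apply(A, 1, stats::var, na.rm = TRUE)
  v2 <- apply(B, 1, stats::var, na.rm = TRUE)
  m <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / m

  if (is.null(fit)) fit <- fitRvm(s2, m)
  if (!is(fit, "RvmFit")) stop("fit must be an RvmFit")
  if (!fit@converged) {
    warning("variance-prior fit did not converge; ",
            "falling back to the ordinary pooled t-test")
    s2_shrunk <- s2
    se <- sqrt(s2 * (1 / n1 + 1 / n2))
    t_stat <- (m1 - m2) / se
    dfree <- m
  } else {
    s2_shrunk <- (m * s2 + 2 / fit@b) / (m + 2 * fit@a)
    se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    t_stat <- (m1 - m2) / se
    dfree <- m + 2 * fit@a
  }
  p <- 2 * stats::pt(-abs(t_stat), dfree)
  data.frame(
    mirna_id = rownames(dct),
    t = t_stat,
    df = dfree,
    p_value = pmin(pmax(p, .Machine$double.xmin), 1),
    s2 = s2,
    s2_shrunk = s2_shrunk,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Validates the p-values and applies the step-up Benjamini-Hochberg
#' procedure (via [stats::p.adjust()]): adjusted values are clipped at 1
#' and nonincreasing when features are ordered by increasing p.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select and orient the differential features
#'
#' Applies the significance and fold-change filters and classifies
#' direction: a kept feature is "up" iff its fold change exceeds 1 and
#' "down" iff below 1; a fold change of exactly 1 is never differential
#' ("ns") regardless of p.
#'
#' @param results data.frame holding at least `mirna_id`, `fold_change`,
#'   `p_value` — typically the merge of [foldChanges()] and [rvmTest()]
#'   as produced by [runPipeline()].
#' @param pThreshold keep features with `p_value` strictly below this.
#' @param fcThreshold keep features with fold change >= `fcThreshold` or
#'   <= `1/fcThreshold` (must be >= 1; 1 disables the filter).
#' @return The filtered rows with a `direction` column, sorted by
#'   decreasing |log2 fold change|.
#' @export
selectDifferential <- function(results, pThreshold = 0.05,
                               fcThreshold = 2) {
  stopifnot(all(c("mirna_id", "fold_change", "p_value") %in% names(results)))
  if (pThreshold <= 0) stop("pThreshold must be positive")
  if (fcThreshold < 1) stop("fcThreshold must be >= 1")
  fc <- results$fold_change
  keep <- results$p_value < pThreshold &
    (fc >= fcThreshold | fc <= 1 / fcThreshold) & fc != 1
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$fold_change > 1, "up", "down")
  out[order(-abs(log2(out$fold_change))), , drop = FALSE]
}
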