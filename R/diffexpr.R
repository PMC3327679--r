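#' Per-feature two-group (or one-sample ratio) linear fit
#'
#' For intensity matrices, computes per feature the mean difference
#' resistant minus sensitive, the pooled residual variance and its degrees of
#' freedom, complete-case per feature. For ratio matrices (one
#' resistant-over-sensitive contrast per column, already collapsed), the fit
#' is the one-sample analogue: mean ratio, sample variance, `n - 1` degrees
#' of freedom.
#'
#' @param mat An `expr_matrix`. Ratio columns are oriented via their dye
#'   annotation before fitting.
#' @return Data frame of class `de_fit` with columns `feature_id`, `logFC`,
#'   `avg_expr`, `s2`, `df`, `v` (unscaled variance of `logFC`, i.e.
#'   `1/n1 + 1/n2` or `1/n`). Features with fewer than two usable samples in a
#'   group are flagged `NA` and excluded from downstream moderation.
#' @export
fit_two_group <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  x <- mat$values
  s <- mat$samples
  if (mat$value_type == "ratio") {
    flip <- s$dye == "Cy3"
    x[, flip] <- -x[, flip, drop = FALSE]
    n <- rowSums(is.finite(x))
    m <- rowMeans(x, na.rm = TRUE)
    s2 <- apply(x, 1, stats::var, na.rm = TRUE)
    ok <- n >= 2
    res <- data.frame(feature_id = rownames(x),
                      logFC = ifelse(ok, m, NA_real_),
                      avg_expr = ifelse(ok, m, NA_real_),
                      s2 = ifelse(ok, s2, NA_real_),
                      df = ifelse(ok, n - 1, NA_real_),
                      v = ifelse(ok, 1 / n, NA_real_),
                      stringsAsFactors = FALSE)
  } else {
    res_cols <- s$condition == "resistant"
    xr <- x[, res_cols, drop = FALSE]
    xs <- x[, !res_cols, drop = FALSE]
    n1 <- rowSums(is.finite(xr)); n2 <- rowSums(is.finite(xs))
    m1 <- rowMeans(xr, na.rm = TRUE); m2 <- rowMeans(xs, na.rm = TRUE)
    v1 <- apply(xr, 1, stats::var, na.rm = TRUE)
    v2 <- apply(xs, 1, stats::var, na.rm = TRUE)
    ok <- n1 >= 2 & n2 >= 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    res <- data.frame(feature_id = rownames(x),
                      logFC = ifelse(ok, m1 - m2, NA_real_),
                      avg_expr = ifelse(ok, (m1 + m2) / 2, NA_real_),
                      s2 = ifelse(ok, s2, NA_real_),
                      df = ifelse(ok, n1 + n2 - 2, NA_real_),
                      v = ifelse(ok, 1 / n1 + 1 / n2, NA_real_),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  class(res) <- c("de_fit", "data.frame")
  res
}

#' Empirical-Bayes prior on residual variances
#'
#' Moment estimator matching the mean and variance of `log(s2)` to the
#' moments of a scaled F/log-chi-square distribution: solves
#' `trigamma(d0/2) = var(e) - mean(trigamma(df/2))` for the prior degrees of
#' freedom `d0` by Newton iteration on the inverse trigamma, then recovers the
#' prior variance `s0_sq`. When the spread of `log(s2)` does not exceed its
#' sampling floor, `d0 = Inf` (complete shrinkage).
#'
#' @param s2 Residual variances (> 0 entries used; needs at least 10).
#' @param df Residual degrees of freedom, recycled to `length(s2)`.
#' @return List of class `eb_prior` with `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & is.finite(df) & s2 > 0 & df > 0
  if (!any(is.finite(s2) & s2 > 0) && any(is.finite(s2)))
    stop("all residual variances are zero; prior unidentifiable")
  if (sum(ok) < 10) stop("need at least 10 features with positive s2")
  z <- log(s2[ok]); d <- df[ok]
  e <- z - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(d / 2))
  if (!is.finite(excess) || excess <= 0) {
    d0 <- Inf
    s0 <- exp(ebar)
  } else {
    d0 <- 2 * .trigamma_inverse(excess)
    s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0), class = "eb_prior")
}

# Newton solve of trigamma(y) = x, y > 0 (tolerance 1e-8).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Moderated t-statistics with shrunken variances
#'
#' Shrinks each residual variance toward the prior,
#' `s_tilde^2 = (d0 * s0^2 + df * s2) / (d0 + df)`, and forms
#' `t = logFC / sqrt(s_tilde^2 * v)` with two-sided p-values from a t
#' distribution on `d0 + df` degrees of freedom. `d0 = 0` (explicit override)
#' reproduces the ordinary pooled t; `d0 = Inf` uses the prior variance and a
#' normal reference.
#'
#' @param fit A `de_fit` from [fit_two_group()].
#' @param prior An `eb_prior`, or a list with `d0` and `s0_sq`.
#' @return `fit` with columns `s_tilde2`, `t_mod`, `p` appended.
#' @export
moderated_t <- function(fit, prior) {
  d0 <- prior$d0; s0 <- prior$s0_sq
  if (!is.finite(s0) || s0 <= 0) stop("prior variance must be > 0")
  if (is.na(d0) || d0 < 0) stop("prior degrees of freedom must be >= 0")
  out <- fit
  if (is.infinite(d0)) {
    out$s_tilde2 <- ifelse(is.na(fit$s2), NA_real_, s0)
  } else {
    out$s_tilde2 <- (d0 * s0 + fit$df * fit$s2) / (d0 + fit$df)
  }
  out$t_mod <- fit$logFC / sqrt(out$s_tilde2 * fit$v)
  out$p <- 2 * stats::pt(-abs(out$t_mod), df = d0 + fit$df)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; missing entries are preserved and
#' excluded from the test count.
#'
#' @param p P-values in \[0, 1\].
#' @return Adjusted values, same order and length as `p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Layer-specific selection thresholds
#'
#' The study-design defaults: mRNA uses FDR <= 0.01 with |logFC| >= 1; miRNA
#' and protein use FDR <= 0.1 with no fold-change gate.
#'
#' @param layer One of "mRNA", "miRNA", "protein".
#' @return List with `fdr_max` and `min_abs_logfc`.
#' @export
de_thresholds <- function(layer = c("mRNA", "miRNA", "protein")) {
  switch(match.arg(layer),
         mRNA = list(fdr_max = 0.01, min_abs_logfc = 1),
         miRNA = list(fdr_max = 0.1, min_abs_logfc = 0),
         protein = list(fdr_max = 0.1, min_abs_logfc = 0))
}

#' Call up/down/not-significant status
#'
#' A feature is `up` when `fdr <= fdr_max` and `logFC >= min_abs_logfc`,
#' `down` when `fdr <= fdr_max` and `logFC <= -min_abs_logfc`, otherwise `ns`
#' (boundary values are included).
#'
#' @param results Data frame with `logFC` and `fdr` columns.
#' @param thresholds List with `fdr_max` in (0, 1] and `min_abs_logfc >= 0`
#'   (see [de_thresholds()]).
#' @return `results` with a `status` column appended.
#' @export
select_differential <- function(results, thresholds) {
  if (!is.numeric(thresholds$fdr_max) || thresholds$fdr_max <= 0 || thresholds$fdr_max > 1)
    stop("fdr_max must be in (0, 1]")
  if (thresholds$min_abs_logfc < 0) stop("min_abs_logfc must be >= 0")
  sig <- !is.na(results$fdr) & results$fdr <= thresholds$fdr_max
  up <- sig & results$logFC >= thresholds$min_abs_logfc & results$logFC > 0
  down <- sig & results$logFC <= -thresholds$min_abs_logfc & results$logFC < 0
  results$status <- ifelse(up, "up", ifelse(down, "down", "ns"))
  results
}

#' Full differential-expression analysis of one layer
#'
#' Fits the per-feature two-group model, estimates the empirical-Bayes prior,
#' computes moderated t-statistics, adjusts for multiple testing and calls
#' status at the layer's thresholds.
#'
#' @param mat A collapsed `expr_matrix`.
#' @param thresholds Selection thresholds; defaults to [de_thresholds()] for
#'   the matrix's layer.
#' @param d0 Optional override of the prior degrees of freedom (`0` disables
#'   shrinkage).
#' @return A data frame of class `de_result` with columns `feature_id`,
#'   `logFC`, `avg_expr`, `s2`, `df`, `v`, `s_tilde2`, `t_mod`, `p`, `fdr`,
#'   `status`; the prior is attached as attribute `prior`.
#' @export
de_analysis <- function(mat, thresholds = de_thresholds(mat$layer), d0 = NULL) {
  fit <- fit_two_group(mat)
  prior <- estimate_prior(fit$s2, fit$df)
  if (!is.null(d0)) prior$d0 <- d0
  res <- moderated_t(fit, prior)
  res$fdr <- bh_fdr(res$p)
  res <- select_differential(res, thresholds)
  attr(res, "prior") <- prior
  attr(res, "thresholds") <- thresholds
  attr(res, "layer") <- mat$layer
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  pr <- attr(x, "prior")
  cat(sprintf("de_result [%s]: %d features (%d up, %d down); prior d0=%s, s0_sq=%.4g\n",
              attr(x, "layer") %||% "?", nrow(x), sum(x$status == "up"),
              sum(x$status == "down"), format(pr$d0, digits = 4), pr$s0_sq))
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  th <- attr(object, "thresholds")
  out <- list(layer = attr(object, "layer"),
              n = nrow(object),
              n_tested = sum(!is.na(object$p)),
              up = sum(object$status == "up"),
              down = sum(object$status == "down"),
              thresholds = th,
              prior = attr(object, "prior"))
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("Differential expression, %s layer\n", x$layer %||% "?"))
  cat(sprintf("  %d features, %d tested; FDR <= %g, |logFC| >= %g\n",
              x$n, x$n_tested, x$thresholds$fdr_max, x$thresholds$min_abs_logfc))
  cat(sprintf("  up: %d  down: %d  ns: %d\n", x$up, x$down, x$n - x$up - x$down))
  cat(sprintf("  prior: d0 = %s, s0_sq = %.4g\n",
              format(x$prior$d0, digits = 4), x$prior$s0_sq))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a differential-expression result table
#'
#' Columns written: `feature_id`, `logFC`, `avg_expr`, `t_mod`, `p`, `fdr`,
#' `status`.
#'
#' @param res A `de_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(res, path) {
  cols <- c("feature_id", "logFC", "avg_expr", "t_mod", "p", "fdr", "status")
  utils::write.table(as.data.frame(res)[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Relative fold change from qRT-PCR cycle thresholds
#'
#' Delta-delta-Ct arithmetic: the target gene's Ct is referenced to the
#' housekeeping gene within each sample, the case is referenced to the
#' control, and the fold change is `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control sample.
#' @return Positive fold change (control = 1).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
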