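#' Normexp background-model parameters
#'
#' Parameters of the normal(background) + exponential(signal) convolution used
#' for background correction of antibody arrays.
#'
#' @param mu Background mean.
#' @param sigma Background standard deviation (> 0).
#' @param alpha Mean of the exponential signal component (> 0).
#' @param offset Non-negative constant added after correction to damp
#'   low-intensity variance.
#' @return An object of class `normexp_params`.
#' @export
normexp_params <- function(mu, sigma, alpha, offset = 16) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(offset) || offset < 0) stop("offset must be >= 0")
  structure(list(mu = mu, sigma = sigma, alpha = alpha, offset = offset),
            class = "normexp_params")
}

#' Estimate normexp parameters by method of moments
#'
#' `mu` and `sigma` come from the moments of the measured local background;
#' `alpha` from the mean of the background-subtracted foreground (the mean of
#' the exponential signal component).
#'
#' @param fg,bg Non-negative foreground and local-background vectors.
#' @param offset Offset to store in the result.
#' @return A `normexp_params`.
#' @export
estimate_normexp_params <- function(fg, bg, offset = 16) {
  ok <- is.finite(fg) & is.finite(bg)
  mu <- mean(bg[ok])
  sigma <- max(stats::sd(bg[ok]), 1e-6)
  alpha <- max(mean(fg[ok] - bg[ok]), sigma / 10, 1e-6)
  normexp_params(mu, sigma, alpha, offset)
}

#' Normexp background correction
#'
#' Returns the conditional expectation of the true signal given the observed
#' foreground under the normal-background + exponential-signal convolution
#' model, plus the offset. All outputs are strictly positive.
#'
#' @param fg Non-negative foreground intensities.
#' @param bg Non-negative local-background intensities (used only when
#'   parameters are estimated).
#' @param params A `normexp_params`, or `"estimate"` to fit them from this
#'   array by [estimate_normexp_params()].
#' @return Positive numeric vector of corrected intensities, same length as
#'   `fg`; missing inputs stay missing.
#' @export
normexp_correct <- function(fg, bg, params = "estimate") {
  if (length(fg) != length(bg)) stop("fg and bg must have the same length")
  if (identical(params, "estimate")) params <- estimate_normexp_params(fg, bg)
  if (!inherits(params, "normexp_params")) params <- do.call(normexp_params, as.list(params))
  out <- rep(NA_real_, length(fg))
  ok <- is.finite(fg)
  par <- c(params$mu, log(params$sigma), log(params$alpha))
  out[ok] <- limma::normexp.signal(par, fg[ok]) + params$offset
  out
}

#' Lowess intensity-dependent normalization of log ratios
#'
#' Removes the smooth trend of the log ratio M on the mean log intensity A by
#' subtracting a robust lowess fit of M on A.
#'
#' @param M Log2 ratios.
#' @param A Mean log2 intensities, same length.
#' @param span Lowess span in (0, 1]; 3 robustness iterations are used.
#' @return `M` minus the fitted trend; pairs with a missing M or A pass
#'   through unchanged.
#' @export
lowess_normalize <- function(M, A, span = 0.3) {
  if (length(M) != length(A)) stop("M and A must have the same length")
  if (!is.numeric(span) || span <= 0 || span > 1) stop("span must be in (0, 1]")
  ok <- is.finite(M) & is.finite(A)
  if (sum(ok) < 10) stop("fewer than 10 finite (M, A) pairs: lowess fit unidentifiable")
  fit <- stats::lowess(A[ok], M[ok], f = span, iter = 3)
  trend <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2, ties = mean)$y
  out <- M
  out[ok] <- M[ok] - trend
  out
}

#' Variance-stabilizing transform for single-channel intensities
#'
#' Per-sample affine calibration (quartiles matched to a virtual reference
#' sample) followed by a generalized-log (arsinh-type) transform
#' `log2((y + sqrt(y^2 + c^2)) / 2)`, which approaches plain `log2` for large
#' intensities. The glog constant `c` is the ratio of the additive to the
#' multiplicative noise standard deviation, estimated from technical-replicate
#' differences when replicate groups are present in the sample metadata.
#'
#' @param mat An `expr_matrix` of raw (non-logged) single-channel intensities.
#' @return An `expr_matrix` of transformed values, same metadata.
#' @export
vsn_like_normalize <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  x <- mat$values
  zero <- apply(x, 2, function(v) all(!is.finite(v) | v == 0))
  if (any(zero))
    stop("sample(s) with all-zero intensities: ",
         paste(colnames(x)[zero], collapse = ", "))
  q <- apply(x, 2, stats::quantile, probs = c(0.25, 0.75), na.rm = TRUE)
  ref <- apply(q, 1, stats::median)
  b <- (q[2, ] - q[1, ]) / (ref[2] - ref[1])
  b[!is.finite(b) | b <= 0] <- 1
  a <- q[1, ] - b * ref[1]
  y <- sweep(sweep(x, 2, a, "-"), 2, b, "/")
  cc <- .glog_constant(y, mat$samples)
  out <- mat
  out$values <- log2((y + sqrt(y^2 + cc^2)) / 2)
  out
}

# Estimate additive (sigma_eps) and multiplicative (sigma_eta) noise sd from
# replicate residuals; variance of the glog transform is flat when
# c = sigma_eps / sigma_eta.
.glog_constant <- function(y, samples) {
  grp <- interaction(samples$condition, samples$bio_rep, drop = TRUE)
  reps <- names(which(table(grp) > 1))
  if (!length(reps)) {
    ## no replicate groups: fall back to a small fraction of the low-intensity
    ## scale so that bright features stay on a plain log2 scale
    pos <- y[is.finite(y) & y > 0]
    return(max(stats::quantile(pos, 0.01) / 5, 1))
  }
  resid <- NULL; mu <- NULL
  for (g in reps) {
    cols <- which(grp == g)
    m <- rowMeans(y[, cols, drop = FALSE], na.rm = TRUE)
    r <- y[, cols, drop = FALSE] - m
    resid <- cbind(resid, r)
    mu <- cbind(mu, matrix(m, nrow = length(m), ncol = length(cols)))
  }
  m_all <- mu[, 1]
  qs <- stats::quantile(m_all, c(0.25, 0.75), na.rm = TRUE)
  lo <- which(m_all <= qs[1]); hi <- which(m_all >= qs[2])
  s_eps <- stats::sd(as.vector(resid[lo, ]), na.rm = TRUE)
  rel <- sweep(resid[hi, , drop = FALSE], 1, m_all[hi], "/")
  s_eta <- stats::sd(as.vector(rel), na.rm = TRUE)
  if (!is.finite(s_eps) || s_eps <= 0) s_eps <- 1
  if (!is.finite(s_eta) || s_eta <= 0) s_eta <- 1e-3
  s_eps / s_eta
}

#' Rank-invariant two-channel normalization
#'
#' Iteratively selects features whose within-channel ranks agree (relative
#' rank difference below `threshold`), fits a lowess curve of the log ratio on
#' the mean log intensity through that invariant set, and subtracts it.
#'
#' @param ch1,ch2 Positive intensity vectors (channel 1 = denominator of the
#'   ratio), equal length >= 20.
#' @param threshold Maximum relative rank difference for the invariant set.
#' @param span Lowess span for the normalization curve.
#' @param max_iter Maximum selection iterations.
#' @param rank_trim Fraction of the rank range excluded at each extreme
#'   before selection (rank invariance is trivially satisfied at the
#'   extremes, where even strongly asymmetric features keep their rank).
#' @return Normalized `log2(ch2/ch1)`; entries with a non-positive or missing
#'   channel are returned as `NA`.
#' @export
rank_invariant_normalize <- function(ch1, ch2, threshold = 0.05, span = 0.4,
                                     max_iter = 10, rank_trim = 0.05) {
  if (length(ch1) != length(ch2)) stop("channels must have the same length")
  if (length(ch1) < 20) stop("need at least 20 features")
  ok <- is.finite(ch1) & is.finite(ch2) & ch1 > 0 & ch2 > 0
  M <- A <- rep(NA_real_, length(ch1))
  M[ok] <- log2(ch2[ok] / ch1[ok])
  A[ok] <- 0.5 * log2(ch1[ok] * ch2[ok])
  sel <- .rank_invariant_set(ch1, ch2, threshold, max_iter, rank_trim)
  if (length(sel) < 10)
    stop("rank-invariant set has fewer than 10 features; consider lowess normalization")
  fit <- stats::lowess(A[sel], M[sel], f = span, iter = 3)
  trend <- stats::approx(fit$x, fit$y, xout = A[ok], rule = 2, ties = mean)$y
  out <- rep(NA_real_, length(ch1))
  out[ok] <- M[ok] - trend
  out
}

# Rank-invariant selection only (shared by the set-level pooled fit).
.rank_invariant_set <- function(ch1, ch2, threshold = 0.05, max_iter = 10,
                                rank_trim = 0.05) {
  ok <- which(is.finite(ch1) & is.finite(ch2) & ch1 > 0 & ch2 > 0)
  sel <- ok
  pr <- (rank(ch1[sel]) + rank(ch2[sel])) / 2 / (length(sel) + 1)
  trimmed <- sel[pr > rank_trim & pr < 1 - rank_trim]
  if (length(trimmed) >= 20) sel <- trimmed
  for (it in seq_len(max_iter)) {
    r1 <- rank(ch1[sel]); r2 <- rank(ch2[sel])
    keep <- abs(r1 - r2) / length(sel) <= threshold
    if (all(keep)) break
    if (sum(keep) < 10) break
    sel <- sel[keep]
  }
  sel
}

#' Filter features with weak signal relative to local background
#'
#' A feature is removed when its foreground falls below its local background
#' in strictly more than `max_fraction` of the arrays in which it is present.
#'
#' @param fg,bg Numeric matrices (features x arrays) of foreground and local
#'   background, same dimensions, feature ids as row names.
#' @param max_fraction Removal threshold on the below-background fraction
#'   (default 0.6; the boundary value itself is kept).
#' @return A list of class `filter_report` with `kept`, `removed` (character
#'   vectors of feature ids) and `fraction` (named below-background fraction).
#' @export
filter_low_signal <- function(fg, bg, max_fraction = 0.6) {
  if (!is.numeric(max_fraction) || max_fraction < 0 || max_fraction > 1)
    stop("max_fraction must be in [0, 1]")
  fg <- as.matrix(fg); bg <- as.matrix(bg)
  if (!identical(dim(fg), dim(bg))) stop("fg and bg must have identical dimensions")
  ids <- rownames(fg)
  if (is.null(ids)) stop("fg must carry feature ids as row names")
  present <- is.finite(fg) & is.finite(bg)
  below <- present & (fg < bg)
  n_present <- rowSums(present)
  frac <- ifelse(n_present > 0, rowSums(below) / n_present, 0)
  names(frac) <- ids
  removed <- ids[frac > max_fraction]
  structure(list(kept = setdiff(ids, removed), removed = removed, fraction = frac),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d kept, %d removed\n",
              length(x$kept), length(x$removed)))
  invisible(x)
}

#' Average foreground/background over the two channels of each array
#'
#' Produces the per-array signal matrices used by [filter_low_signal()] for
#' two-color data.
#'
#' @param set A `two_color_set`.
#' @return List with matrices `fg` and `bg` (features x arrays).
#' @export
two_color_signal_matrices <- function(set) {
  fg <- sapply(set$arrays, function(a) (a$fg1 + a$fg2) / 2)
  bg <- sapply(set$arrays, function(a) (a$bg1 + a$bg2) / 2)
  rownames(fg) <- rownames(bg) <- set$feature_ids
  list(fg = fg, bg = bg)
}

#' Background-correct and normalize a two-color array set to log ratios
#'
#' For each array the two channels are background-corrected, oriented as
#' Cy5 over Cy3, and the log ratio is normalized by the chosen method. The
#' result is a ratio-type [expression_matrix()] with one column per array; the
#' per-array `dye` annotation records the dye of the resistant-condition
#' channel, which [collapse_replicates()] uses to undo dye swaps.
#'
#' @param set A `two_color_set`.
#' @param background "subtract" (background-subtracted, floored at 0.5),
#'   "normexp" (see [normexp_correct()]), or "none".
#' @param normalization "lowess" (per-array robust fit of M on A),
#'   "rank_invariant" (a single curve fitted to the pooled rank-invariant
#'   sets of all arrays in raw Cy5/Cy3 orientation, so that with a balanced
#'   dye-swap design selection artifacts cancel while true dye bias is
#'   retained), or "none".
#' @param layer Omics layer label for the result.
#' @param keep_features Optional feature ids to retain (e.g. the `kept` set of
#'   a [filter_low_signal()] report).
#' @param span Lowess span.
#' @param offset Normexp offset.
#' @return An `expr_matrix` with `value_type = "ratio"`.
#' @export
process_two_color <- function(set, background = c("subtract", "normexp", "none"),
                              normalization = c("lowess", "rank_invariant", "none"),
                              layer = "mRNA", keep_features = NULL,
                              span = 0.3, offset = 16) {
  background <- match.arg(background)
  normalization <- match.arg(normalization)
  ids <- set$feature_ids
  sub <- if (is.null(keep_features)) seq_along(ids) else match(intersect(ids, keep_features), ids)
  ids <- ids[sub]
  meta <- set$array_meta
  vals <- matrix(NA_real_, length(ids), nrow(meta),
                 dimnames = list(ids, meta$array_id))
  correct <- switch(background,
    subtract = function(fg, bg) pmax(fg - bg, 0.5),
    normexp = function(fg, bg) normexp_correct(fg, bg, estimate_normexp_params(fg, bg, offset)),
    none = function(fg, bg) pmax(fg, 0.5))
  Ms <- As <- sets <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    a <- lapply(set$arrays[[i]], `[`, sub)
    i1 <- correct(a$fg1, a$bg1)
    i2 <- correct(a$fg2, a$bg2)
    if (meta$dye_of_channel1[i] == "Cy5") { cy5 <- i1; cy3 <- i2 } else { cy5 <- i2; cy3 <- i1 }
    M <- log2(cy5 / cy3)
    A <- 0.5 * log2(cy5 * cy3)
    if (normalization == "lowess") {
      vals[, i] <- lowess_normalize(M, A, span = span)
    } else {
      Ms[[i]] <- M; As[[i]] <- A
      if (normalization == "rank_invariant")
        sets[[i]] <- .rank_invariant_set(cy3, cy5)
    }
  }
  if (normalization == "rank_invariant") {
    pa <- unlist(Map(`[`, As, sets)); pm <- unlist(Map(`[`, Ms, sets))
    if (length(pa) < 10)
      stop("rank-invariant set has fewer than 10 features; consider lowess normalization")
    fit <- stats::lowess(pa, pm, f = span, iter = 3)
    for (i in seq_len(nrow(meta))) {
      ok <- is.finite(Ms[[i]]) & is.finite(As[[i]])
      trend <- stats::approx(fit$x, fit$y, xout = As[[i]][ok], rule = 2, ties = mean)$y
      v <- Ms[[i]]; v[ok] <- v[ok] - trend
      vals[, i] <- v
    }
  } else if (normalization == "none") {
    for (i in seq_len(nrow(meta))) vals[, i] <- Ms[[i]]
  }
  dye_res <- ifelse(meta$condition_ch1 == "resistant", meta$dye_of_channel1,
                    ifelse(meta$dye_of_channel1 == "Cy5", "Cy3", "Cy5"))
  samples <- data.frame(sample_id = meta$array_id, condition = "resistant",
                        bio_rep = meta$bio_rep, tech_rep = meta$tech_rep,
                        dye = dye_res, stringsAsFactors = FALSE)
  expression_matrix(vals, samples, layer = layer, value_type = "ratio")
}

#' Collapse technical replicates to one column per biological replicate
#'
#' Ratio columns are first sign-flipped to a common orientation (positive =
#' resistant over sensitive) using the dye annotation, then technical
#' replicates sharing (condition, biological replicate) are averaged with
#' missing values ignored.
#'
#' @param mat An `expr_matrix`.
#' @return An `expr_matrix` with one column per (condition, biological
#'   replicate); collapsed ratio columns carry the canonical `dye = "Cy5"`.
#' @export
collapse_replicates <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  s <- mat$samples
  x <- mat$values
  if (mat$value_type == "ratio") {
    if (any(is.na(s$dye) | !s$dye %in% c("Cy3", "Cy5")))
      stop("inconsistent dye annotation on ratio columns")
    flip <- s$dye == "Cy3"
    x[, flip] <- -x[, flip, drop = FALSE]
  } else if (any(is.na(s$dye))) {
    stop("inconsistent dye annotation")
  }
  grp <- paste(s$condition, s$bio_rep, sep = ".")
  ug <- unique(grp)
  out <- sapply(ug, function(g) rowMeans(x[, grp == g, drop = FALSE], na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out <- matrix(out, nrow = nrow(x), dimnames = list(rownames(x), ug))
  first <- match(ug, grp)
  samples <- data.frame(sample_id = ug, condition = s$condition[first],
                        bio_rep = s$bio_rep[first], tech_rep = 1L,
                        dye = if (mat$value_type == "ratio") "Cy5" else "none",
                        stringsAsFactors = FALSE)
  expression_matrix(out, samples, layer = mat$layer, value_type = mat$value_type)
}
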