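# Vertex-wise general linear model, severity correlations, and effect-size
# maps.

#' Vertex-wise ordinary least squares GLM
#'
#' Fits `y_v = X b_v + e` independently at every vertex and tests the linear
#' contrast `c' b_v` with a two-sided Student t test on `n - p` residual
#' degrees of freedom. Vertices with missing subject values are fitted on
#' their complete cases (listwise per vertex); vertices where fewer than
#' `min_prop` of subjects (and fewer than `p + 2` subjects) contribute are
#' returned as missing. Vertices with (numerically) zero residual variance
#' are flagged `degenerate` with `p = NA`.
#'
#' @param Y subjects x vertices response matrix.
#' @param X subjects x p design matrix (include the intercept explicitly);
#'   must have full column rank.
#' @param contrast numeric contrast vector of length p.
#' @param min_prop minimum fraction of subjects that must contribute for a
#'   vertex to be analyzed (default 0.9).
#' @return object of class `vertex_glm` with per-vertex `beta` (contrast
#'   effect), `t`, `p`, `df`, `n_used`, a `degenerate` flag vector, and the
#'   full coefficient matrix `coefficients` (p x V).
#' @export
glm_fit <- function(Y, X, contrast, min_prop = 0.9) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  n <- nrow(Y)
  V <- ncol(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design rows must match subjects")
  if (length(contrast) != p) stop("contrast length must match design columns")
  if (n < p + 2L) stop("need n > p + 1 subjects")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, p)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  beta_full <- matrix(NA_real_, p, V)
  tval <- pval <- cb <- rep(NA_real_, V)
  n_used <- integer(V)
  degenerate <- rep(FALSE, V)
  dfree <- rep(NA_real_, V)

  XtXinv <- chol2inv(qr.R(qx))
  cvc <- drop(t(contrast) %*% XtXinv %*% contrast)

  complete <- !colSums(is.na(Y))
  if (any(complete)) {
    idx <- which(complete)
    B <- qr.coef(qx, Y[, idx, drop = FALSE])
    res <- Y[, idx, drop = FALSE] - X %*% B
    rss <- colSums(res^2)
    df <- n - p
    s2 <- rss / df
    cbv <- as.vector(contrast %*% B)
    scale_y <- colMeans(Y[, idx, drop = FALSE]^2)
    degen <- s2 <= 1e-24 * pmax(scale_y, 1e-300)
    tv <- cbv / sqrt(s2 * cvc)
    pv <- 2 * stats::pt(-abs(tv), df)
    tv[degen] <- NA_real_
    pv[degen] <- NA_real_
    beta_full[, idx] <- B
    cb[idx] <- cbv
    tval[idx] <- tv
    pval[idx] <- pv
    degenerate[idx] <- degen
    n_used[idx] <- n
    dfree[idx] <- df
  }
  incomplete <- which(!complete)
  for (v in incomplete) {
    ok <- !is.na(Y[, v])
    m <- sum(ok)
    if (m < max(p + 2L, ceiling(min_prop * n))) next
    qv <- qr(X[ok, , drop = FALSE])
    if (qv$rank < p) next
    b <- qr.coef(qv, Y[ok, v])
    res <- Y[ok, v] - X[ok, , drop = FALSE] %*% b
    df <- m - p
    s2 <- sum(res^2) / df
    xtxi <- chol2inv(qr.R(qv))
    cv <- drop(t(contrast) %*% xtxi %*% contrast)
    beta_full[, v] <- b
    cb[v] <- sum(contrast * b)
    n_used[v] <- m
    dfree[v] <- df
    if (s2 <= 1e-24 * max(mean(Y[ok, v]^2), 1e-300)) {
      degenerate[v] <- TRUE
      next
    }
    tval[v] <- cb[v] / sqrt(s2 * cv)
    pval[v] <- 2 * stats::pt(-abs(tval[v]), df)
  }

  structure(list(beta = cb, t = tval, p = pval, df = dfree,
                 n_used = n_used, degenerate = degenerate,
                 coefficients = beta_full, contrast = contrast,
                 design_columns = colnames(X)),
            class = "vertex_glm")
}

#' @export
print.vertex_glm <- function(x, ...) {
  ok <- !is.na(x$t)
  cat(sprintf("vertex_glm: %d/%d vertices analyzed, |t| max %.2f, min p %.2g\n",
              sum(ok | x$degenerate), length(x$t),
              if (any(ok)) max(abs(x$t[ok])) else NA,
              if (any(ok)) min(x$p[ok]) else NA))
  invisible(x)
}

#' Vertex-wise correlation with a continuous predictor
#'
#' Regresses each vertex on a continuous predictor (e.g. a disease-severity
#' or MMSE score) adjusting for nuisance covariates, and tests the predictor
#' slope. A positive `t` means the vertex value increases with the predictor.
#'
#' @param Y subjects x vertices matrix.
#' @param predictor numeric vector (must vary across subjects).
#' @param nuisance optional numeric nuisance design (no intercept column).
#' @param min_prop see [glm_fit()].
#' @return a `vertex_glm` on the predictor contrast.
#' @export
correlation_analysis <- function(Y, predictor, nuisance = NULL, min_prop = 0.9) {
  predictor <- as.numeric(predictor)
  if (stats::var(predictor, na.rm = TRUE) == 0 || all(is.na(predictor)))
    stop("predictor is constant: correlation analysis is undefined")
  X <- cbind(intercept = 1, predictor = predictor)
  if (!is.null(nuisance)) X <- cbind(X, as.matrix(nuisance))
  contrast <- c(0, 1, rep(0, ncol(X) - 2L))
  glm_fit(Y, X, contrast, min_prop = min_prop)
}

#' Vertex-wise Cohen's d between two groups
#'
#' Standardized mean difference `(mean_1 - mean_2) / pooled SD` per vertex,
#' by default computed on residuals after regressing out nuisance covariates
#' (fitted across all subjects, group excluded from the nuisance model so the
#' group difference is preserved).
#'
#' @param Y subjects x vertices matrix.
#' @param group factor with exactly two levels; d is level-1 minus level-2.
#' @param nuisance optional nuisance design (no intercept column).
#' @param residualize adjust for nuisance before computing d (default `TRUE`).
#' @return object of class `effect_size_map`: numeric vector of d values with
#'   `NA` where the pooled SD is zero or data are missing.
#' @export
cohens_d <- function(Y, group, nuisance = NULL, residualize = TRUE) {
  Y <- as.matrix(Y)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  n1 <- sum(group == levels(group)[1L])
  n2 <- sum(group == levels(group)[2L])
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  R <- Y
  if (residualize && !is.null(nuisance)) {
    X <- cbind(1, as.matrix(nuisance))
    cc <- !colSums(is.na(Y))
    if (any(cc)) {
      B <- qr.coef(qr(X), Y[, cc, drop = FALSE])
      R[, cc] <- Y[, cc, drop = FALSE] - X %*% B
    }
    for (v in which(!cc)) {
      ok <- !is.na(Y[, v])
      if (sum(ok) < ncol(X) + 2L) next
      b <- qr.coef(qr(X[ok, , drop = FALSE]), Y[ok, v])
      R[ok, v] <- Y[ok, v] - drop(X[ok, , drop = FALSE] %*% b)
    }
  }
  g1 <- group == levels(group)[1L]
  m1 <- colMeans(R[g1, , drop = FALSE], na.rm = TRUE)
  m2 <- colMeans(R[!g1, , drop = FALSE], na.rm = TRUE)
  v1 <- apply(R[g1, , drop = FALSE], 2L, stats::var, na.rm = TRUE)
  v2 <- apply(R[!g1, , drop = FALSE], 2L, stats::var, na.rm = TRUE)
  k1 <- colSums(!is.na(R[g1, , drop = FALSE]))
  k2 <- colSums(!is.na(R[!g1, , drop = FALSE]))
  pooled <- sqrt(((k1 - 1) * v1 + (k2 - 1) * v2) / pmax(k1 + k2 - 2, 1))
  d <- (m1 - m2) / pooled
  d[!is.finite(d)] <- NA_real_
  structure(d, class = "effect_size_map",
            groups = levels(group), n = c(n1, n2))
}

#' @export
print.effect_size_map <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("effect_size_map (%s vs %s): d range [%.2f, %.2f], %d missing\n",
              g[1L], g[2L], min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              sum(is.na(x))))
  invisible(x)
}

#' Net effect size map
#'
#' Per-vertex difference of the effect-size magnitudes of the two metrics,
#' `|d_md| - |d_ct|`, restricted to a significance mask (the union of
#' FWE-significant vertices from either metric). Positive values mark cortex
#' where mean diffusivity carries the larger effect; negative values mark
#' cortex where thickness does. Vertices outside the mask are missing.
#'
#' @param d_md,d_ct per-vertex Cohen's d maps of equal length.
#' @param sig_mask integer vertex ids (or logical vector) defining where the
#'   net effect size is computed.
#' @return numeric vector with `NA` outside the mask.
#' @export
net_effect_size <- function(d_md, d_ct, sig_mask) {
  nv <- length(d_md)
  if (length(d_ct) != nv) stop("effect-size maps have different lengths")
  if (is.logical(sig_mask)) {
    if (length(sig_mask) != nv) stop("logical mask length mismatch")
    sig_mask <- which(sig_mask)
  }
  sig_mask <- as.integer(sig_mask)
  if (length(sig_mask) && (min(sig_mask) < 1L || max(sig_mask) > nv))
    stop("sig_mask references vertices outside the maps")
  out <- rep(NA_real_, nv)
  out[sig_mask] <- abs(d_md[sig_mask]) - abs(d_ct[sig_mask])
  out
}
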