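# Parametric empirical-Bayes harmonization of site effects (ComBat).
# Per vertex v and site i the model is
#   y_ijv = alpha_v + x_j' beta_v + gamma_iv + delta_iv * eps_ijv,
# with normal/inverse-gamma priors on the site location and scale parameters.
# Fitting and adjustment are split so a model can be serialized and re-applied.

#' Fit a ComBat harmonization model
#'
#' Estimates, per vertex: the grand intercept and covariate effects by least
#' squares (site indicator effects constrained to a sample-size-weighted zero
#' sum), the pooled residual scale, and per-site location/scale parameters
#' shrunk by parametric empirical Bayes (normal prior on locations,
#' inverse-gamma prior on scales, hyperparameters by method of moments,
#' iterated to convergence).
#'
#' Vertices with missing values are excluded from hyperprior estimation; their
#' site parameters are estimated from their complete subjects and shrunk with
#' the hyperpriors of the complete vertices, and they are flagged in
#' `model$qc$incomplete_vertices`.
#'
#' @param data numeric subjects x vertices matrix (e.g. smoothed cortical MD).
#' @param site factor (or coercible) of site labels, one per subject; at least
#'   two sites with at least two subjects each.
#' @param covariates optional numeric design matrix (subjects x q, no
#'   intercept) of biological covariates whose effects must be preserved
#'   (typically group, age, sex, handedness).
#' @param eb use empirical-Bayes shrinkage (`TRUE`, the parametric ComBat);
#'   `FALSE` uses the raw per-site location/scale estimates.
#' @param tol convergence tolerance on the EB updates (max absolute change).
#' @param maxit iteration cap for the EB updates.
#' @return object of class `combat_model`.
#' @export
combat_fit <- function(data, site, covariates = NULL, eb = TRUE,
                       tol = 1e-6, maxit = 100L) {
  data <- as.matrix(data)
  site <- factor(site)
  n <- nrow(data)
  V <- ncol(data)
  if (length(site) != n) stop("site labels must match data rows")
  if (nlevels(site) < 2L)
    stop("all subjects share one site label: nothing to harmonize across")
  n_i <- table(site)
  if (any(n_i < 2L))
    stop("site(s) with a single subject cannot be harmonized: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must match data rows")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  }

  Zs <- stats::model.matrix(~ site - 1)      # n x k site indicators
  colnames(Zs) <- levels(site)
  X <- cbind(Zs, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("design is rank deficient; confounded columns: ",
         paste(bad, collapse = ", "))
  }
  k <- nlevels(site)
  q <- if (is.null(covariates)) 0L else ncol(covariates)

  complete <- !colSums(is.na(data))
  if (!any(complete)) stop("no complete vertices to fit the model on")

  B <- matrix(NA_real_, ncol(X), V, dimnames = list(colnames(X), NULL))
  B[, complete] <- qr.coef(qx, data[, complete, drop = FALSE])
  if (any(!complete)) {
    for (v in which(!complete)) {
      ok <- !is.na(data[, v])
      if (sum(ok) < ncol(X) + 1L) next
      site_ok <- droplevels(site[ok])
      if (nlevels(site_ok) < k || any(table(site_ok) < 2L)) next
      B[, v] <- qr.coef(qr(X[ok, , drop = FALSE]), data[ok, v])
    }
  }
  fitted_v <- !is.na(B[1L, ])

  wts <- as.numeric(n_i) / n
  alpha <- as.vector(wts %*% B[1:k, , drop = FALSE])   # weighted grand mean
  beta <- if (q) B[(k + 1):(k + q), , drop = FALSE] else
    matrix(0, 0L, V)

  stand_mean <- matrix(alpha, n, V, byrow = TRUE)
  if (q) stand_mean <- stand_mean + covariates %*% beta
  resid <- data - X %*% B
  sigma2 <- colSums(resid^2, na.rm = TRUE) /
    pmax(colSums(!is.na(resid)), 1L)                    # pooled, MLE scaling
  sigma <- sqrt(sigma2)
  degen <- fitted_v & sigma2 <= 0
  sigma[degen] <- NA_real_

  Zmat <- (data - stand_mean) / matrix(sigma, n, V, byrow = TRUE)

  gamma_hat <- matrix(NA_real_, k, V, dimnames = list(levels(site), NULL))
  delta2_hat <- matrix(NA_real_, k, V, dimnames = list(levels(site), NULL))
  for (i in seq_len(k)) {
    rows <- site == levels(site)[i]
    zi <- Zmat[rows, , drop = FALSE]
    gamma_hat[i, ] <- colMeans(zi, na.rm = TRUE)
    m <- colSums(!is.na(zi))
    dv <- colSums(sweep(zi, 2L, gamma_hat[i, ], "-")^2, na.rm = TRUE) /
      pmax(m - 1L, 1L)
    dv[m < 2L] <- NA_real_
    delta2_hat[i, ] <- dv
  }

  usable <- complete & fitted_v & !degen
  hyper <- vector("list", k)
  names(hyper) <- levels(site)
  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_len(k)) {
    gh <- gamma_hat[i, usable]
    d2 <- delta2_hat[i, usable]
    g_bar <- mean(gh)
    t2 <- stats::var(gh)
    md <- mean(d2)
    s2 <- stats::var(d2)
    a_prior <- (2 * s2 + md^2) / s2
    b_prior <- (md * s2 + md^3) / s2
    hyper[[i]] <- list(gamma_bar = g_bar, tau2_bar = t2,
                       lambda_bar = a_prior, theta_bar = b_prior)
    if (!eb) next
    vfit <- which(fitted_v & !degen)
    rows <- which(site == levels(site)[i])
    Zi <- Zmat[rows, vfit, drop = FALSE]
    m <- colSums(!is.na(Zi))
    g_hat <- gamma_hat[i, vfit]
    d_old <- delta2_hat[i, vfit]
    d_old[is.na(d_old)] <- 1
    g_new <- g_hat
    Zi0 <- Zi
    Zi0[is.na(Zi0)] <- 0
    nonmiss <- !is.na(Zi)
    for (it in seq_len(maxit)) {
      g_prev <- g_new
      d_prev <- d_old
      g_new <- (t2 * m * g_hat + d_old * g_bar) / (t2 * m + d_old)
      sum2 <- colSums(Zi0^2) - 2 * g_new * colSums(Zi0) + m * g_new^2
      d_old <- (0.5 * sum2 + b_prior) / (m / 2 + a_prior - 1)
      if (max(abs(g_new - g_prev), abs(d_old - d_prev)) < tol) break
    }
    gamma_star[i, vfit] <- g_new
    delta2_star[i, vfit] <- d_old
  }
  if (!eb) {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
  }

  structure(list(alpha = alpha, beta = beta, sigma = sigma,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 hyper = hyper, sites = levels(site),
                 n_per_site = as.integer(n_i),
                 covariate_names = colnames(covariates),
                 eb = eb,
                 qc = list(incomplete_vertices = which(!complete),
                           unfitted_vertices = which(!fitted_v),
                           degenerate_vertices = which(degen))),
            class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("combat_model: %d sites (%s), %d vertices, %s covariates, EB %s\n",
              length(x$sites), paste(x$sites, collapse = ", "),
              length(x$alpha),
              if (length(x$covariate_names)) paste(x$covariate_names, collapse = "+") else "no",
              if (x$eb) "on" else "off"))
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Adjusts the data to the pooled location/scale:
#' `y* = sigma_v * (z - gamma*_iv) / delta*_iv + alpha_v + x' beta_v`,
#' which removes the site location shift and rescales the site residual
#' spread while leaving the covariate-projected component untouched.
#'
#' @param data subjects x vertices matrix, same vertex set as the model.
#' @param model a [combat_fit()] result.
#' @param site site labels for the rows of `data`; must all be known to the
#'   model.
#' @param covariates covariate matrix matching the model's covariates.
#' @return harmonized matrix of the same shape.
#' @export
combat_apply <- function(data, model, site, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  data <- as.matrix(data)
  site <- as.character(site)
  n <- nrow(data)
  V <- ncol(data)
  if (V != length(model$alpha)) stop("vertex count does not match model")
  if (length(site) != n) stop("site labels must match data rows")
  unseen <- setdiff(unique(site), model$sites)
  if (length(unseen))
    stop("site(s) not present in the harmonization model: ",
         paste(unseen, collapse = ", "))
  q <- nrow(model$beta)
  if (q) {
    if (is.null(covariates)) stop("covariates must match the model's covariate set")
    covariates <- as.matrix(covariates)
    if (ncol(covariates) != q || nrow(covariates) != n)
      stop("covariates must match the model's covariate set")
  }
  stand_mean <- matrix(model$alpha, n, V, byrow = TRUE)
  if (q) stand_mean <- stand_mean + covariates %*% model$beta
  sig <- matrix(model$sigma, n, V, byrow = TRUE)
  Z <- (data - stand_mean) / sig
  si <- match(site, model$sites)
  out <- sig * (Z - model$gamma_star[si, , drop = FALSE]) /
    sqrt(model$delta2_star[si, , drop = FALSE]) + stand_mean
  dimnames(out) <- dimnames(data)
  out
}

#' Serialize a ComBat model to JSON
#'
#' @param model a `combat_model`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_combat_model <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  x <- unclass(model)
  x$beta <- list(dim = dim(model$beta), values = as.vector(model$beta))
  for (f in c("gamma_star", "delta2_star", "gamma_hat", "delta2_hat"))
    x[[f]] <- list(dim = dim(model[[f]]), values = as.vector(model[[f]]))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a serialized ComBat model
#'
#' @param path file written by [write_combat_model()].
#' @return a `combat_model`.
#' @export
read_combat_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("beta", "gamma_star", "delta2_star", "gamma_hat", "delta2_hat")) {
    x[[f]] <- matrix(as.numeric(x[[f]]$values), x[[f]]$dim[1L], x[[f]]$dim[2L])
  }
  rownames(x$gamma_star) <- rownames(x$delta2_star) <- x$sites
  x$alpha <- as.numeric(x$alpha)
  x$sigma <- as.numeric(x$sigma)
  x$hyper <- lapply(x$hyper, function(h) lapply(h, as.numeric))
  structure(x, class = "combat_model")
}
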