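#' Build a design matrix over staged groups
#'
#' Three parameterizations are supported:
#' \describe{
#'   \item{baseline}{intercept (controls as baseline) plus one indicator per
#'     stage I--IV; stage coefficients are log fold-changes vs control.}
#'   \item{cellmeans}{one indicator per group (control, I--IV), no
#'     intercept; each coefficient is a group mean. Spans the same column
#'     space as `baseline`.}
#'   \item{numeric}{intercept plus a numeric stage covariate coded
#'     control = 0, I = 1, ..., IV = 4, for ordered-trend modelling.}
#' }
#'
#' @param groups Character or factor vector of group labels, values in
#'   `control`, `I`, `II`, `III`, `IV`.
#' @param kind One of `"baseline"`, `"cellmeans"`, `"numeric"`.
#' @return Numeric design matrix (samples x terms) with a `kind` attribute.
#' @export
build_design <- function(groups, kind = c("baseline", "cellmeans", "numeric")) {
  kind <- match.arg(kind)
  groups <- as.character(groups)
  bad <- setdiff(unique(groups), stage_levels())
  if (length(bad) > 0 || anyNA(groups)) {
    stop("unknown group label(s): ",
         paste(c(bad, if (anyNA(groups)) "NA"), collapse = ", "),
         call. = FALSE)
  }
  n <- length(groups)
  X <- switch(kind,
    baseline = {
      m <- cbind(intercept = rep(1, n),
                 vapply(tumor_stages(), function(s) as.numeric(groups == s),
                        numeric(n)))
      colnames(m) <- c("intercept", paste0("stage", tumor_stages()))
      m
    },
    cellmeans = {
      m <- vapply(stage_levels(), function(s) as.numeric(groups == s),
                  numeric(n))
      colnames(m) <- stage_levels()
      m
    },
    numeric = cbind(intercept = rep(1, n),
                    stage_num = match(groups, stage_levels()) - 1))
  attr(X, "kind") <- kind
  X
}

#' Fit per-gene (weighted) least-squares models
#'
#' Fits the given design to every gene's log2 expression by ordinary or
#' weighted least squares. The fit is deterministic; with per-observation
#' precision weights (e.g. from [estimate_meanvar_weights()]) each gene is
#' solved separately with its own weight vector.
#'
#' @param dataset A [stage_dataset()].
#' @param design Design matrix from [build_design()] (rows = samples).
#' @param weights Optional positive weight matrix, genes x samples.
#' @return An object of class `gene_fits`: per-gene coefficients, residual
#'   variances `sigma2`, residual degrees of freedom, unscaled coefficient
#'   standard deviations (sqrt of the diagonal of \eqn{(X'WX)^{-1}}), the
#'   unscaled covariance, residual sums of squares for the full and
#'   intercept-only models, and average log2 expression.
#' @export
fit_gene_models <- function(dataset, design, weights = NULL) {
  stopifnot(inherits(dataset, "stage_dataset"))
  Y <- dataset$exprs
  X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X); G <- nrow(Y)
  if (ncol(Y) != n) {
    stop("design has ", n, " rows but dataset has ", ncol(Y), " samples",
         call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == dim(Y)) || any(weights <= 0)) {
      stop("`weights` must be a positive genes x samples matrix",
           call. = FALSE)
    }
  }
  df_residual <- n - p

  if (is.null(weights)) {
    coef <- t(qr.coef(qrX, t(Y)))
    res <- Y - coef %*% t(X)
    rss <- rowSums(res^2)
    mu0 <- rowMeans(Y)
    rss0 <- rowSums((Y - mu0)^2)
    cov_unscaled <- chol2inv(chol(crossprod(X)))
    stdev_unscaled <- matrix(sqrt(diag(cov_unscaled)), G, p, byrow = TRUE)
  } else {
    coef <- matrix(NA_real_, G, p)
    rss <- rss0 <- numeric(G)
    cov_unscaled <- array(NA_real_, c(p, p, G))
    stdev_unscaled <- matrix(NA_real_, G, p)
    for (g in seq_len(G)) {
      w <- weights[g, ]
      f <- stats::lm.wfit(X, Y[g, ], w)
      coef[g, ] <- f$coefficients
      rss[g] <- sum(w * f$residuals^2)
      mu0 <- sum(w * Y[g, ]) / sum(w)
      rss0[g] <- sum(w * (Y[g, ] - mu0)^2)
      cu <- chol2inv(chol(crossprod(sqrt(w) * X)))
      cov_unscaled[, , g] <- cu
      stdev_unscaled[g, ] <- sqrt(diag(cu))
    }
  }
  sigma2 <- if (df_residual > 0) rss / df_residual else rep(NA_real_, G)
  dimnames(coef) <- list(rownames(Y), colnames(X))
  colnames(stdev_unscaled) <- colnames(X)

  structure(list(coefficients = coef, sigma2 = sigma2,
                 df_residual = df_residual,
                 stdev_unscaled = stdev_unscaled,
                 cov_unscaled = cov_unscaled,
                 rss = rss, rss0 = rss0,
                 amean = rowMeans(Y),
                 design = X, kind = attr(design, "kind"),
                 weighted = !is.null(weights),
                 genes = rownames(Y)),
            class = "gene_fits")
}

#' Fitted values of per-gene models
#'
#' @param object A `gene_fits` object.
#' @param ... Unused.
#' @return Genes x samples matrix of fitted log2 expression.
#' @export
fitted.gene_fits <- function(object, ...) {
  object$coefficients %*% t(object$design)
}

#' @export
print.gene_fits <- function(x, ...) {
  cat("<gene_fits> ", nrow(x$coefficients), " genes, design `", x$kind,
      "` (", ncol(x$coefficients), " terms), residual df ", x$df_residual,
      if (x$weighted) ", precision-weighted" else "", "\n", sep = "")
  invisible(x)
}

#' Mean-variance precision weights
#'
#' Fits the design once unweighted, then models the mean-variance
#' relationship by locally weighted regression of the square root of the
#' residual standard deviation on average log2 expression. Each
#' observation's weight is the trend prediction at its fitted value raised
#' to the -4th power, i.e. the inverse predicted variance on the sqrt-SD
#' scale. With already-normalized log2 microarray/RSEM-style input the true
#' trend is often nearly flat, in which case the weights are close to
#' constant and weighting is inconsequential.
#'
#' @param dataset A [stage_dataset()].
#' @param design Design matrix from [build_design()].
#' @param span Smoother span passed to [stats::lowess()].
#' @return Positive weight matrix, genes x samples.
#' @export
estimate_meanvar_weights <- function(dataset, design, span = 0.5) {
  fit <- fit_gene_models(dataset, design)
  ok <- is.finite(fit$sigma2) & fit$df_residual > 0
  if (sum(ok) < 10) {
    warning("fewer than 10 genes with residual variance; ",
            "mean-variance trend unfittable, using unit weights",
            call. = FALSE)
    return(matrix(1, nrow(dataset$exprs), ncol(dataset$exprs),
                  dimnames = dimnames(dataset$exprs)))
  }
  sx <- fit$amean[ok]
  sy <- sqrt(sqrt(pmax(fit$sigma2[ok], 1e-12)))
  trend <- stats::lowess(sx, sy, f = span)
  mu <- fitted(fit)
  pred <- stats::approx(trend$x, trend$y, xout = mu, rule = 2,
                        ties = "ordered")$y
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^-4, nrow(mu), ncol(mu), dimnames = dimnames(dataset$exprs))
  w
}

# Solve trigamma(x) = y (Newton iteration on the monotone decreasing
# trigamma), used to match the variance of log residual variances.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# Method-of-moments fit of the scaled-inverse-chi-square variance prior:
# matches the mean and variance of log residual variances against the
# scaled-F marginal of the hierarchical model (digamma/trigamma matching).
fit_variance_prior <- function(sigma2, df) {
  s2 <- pmax(sigma2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    # no excess dispersion beyond sampling: fully pooled variance
    df_prior <- Inf
    var_prior <- mean(s2)
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Empirical-Bayes moderation of per-gene statistics
#'
#' Estimates the variance-prior hyperparameters (prior df \eqn{d_0}, prior
#' variance \eqn{s_0^2}) by method of moments on the log residual variances,
#' shrinks each gene's variance to the posterior
#' \eqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, and forms moderated
#' t-statistics per coefficient (df \eqn{d_0 + d}) and a moderated F for the
#' joint test of all non-intercept terms against an intercept-only model.
#' P-values are BH-adjusted per statistic family across genes.
#'
#' @param fits A `gene_fits` object from [fit_gene_models()]; at least 2
#'   genes with positive residual df are required. `prior_df` may be
#'   supplied to override estimation (0 recovers ordinary t-statistics;
#'   `Inf` fully pools to the prior variance).
#' @param prior_df,prior_var Optional fixed hyperparameters; both must be
#'   given to skip estimation (if only `prior_df` is given, `prior_var` is
#'   estimated with the prior df fixed).
#' @return An object of class `moderated_stats` with fields `df_prior`,
#'   `var_prior`, `var_post`, matrices `t`, `p`, `adj_p` (genes x terms),
#'   the joint `F`, `F_p`, `F_adj_p`, and the coefficient matrix.
#' @export
ebayes_moderate <- function(fits, prior_df = NULL, prior_var = NULL) {
  stopifnot(inherits(fits, "gene_fits"))
  d <- fits$df_residual
  if (d <= 0) stop("no residual degrees of freedom: variance cannot be ",
                   "estimated (saturated model)", call. = FALSE)
  if (sum(is.finite(fits$sigma2)) < 2) {
    stop("moderation needs at least 2 genes with residual variance",
         call. = FALSE)
  }
  s2 <- pmax(fits$sigma2, 1e-12)

  if (is.null(prior_df) || is.null(prior_var)) {
    est <- fit_variance_prior(s2, d)
    if (is.null(prior_df)) prior_df <- est$df_prior
    if (is.null(prior_var)) {
      prior_var <- if (identical(prior_df, est$df_prior) || prior_df == 0) {
        est$var_prior
      } else {
        # re-solve the mean equation with the fixed prior df
        e <- log(s2) - digamma(d / 2) + log(d / 2)
        if (is.finite(prior_df)) {
          exp(mean(e) + digamma(prior_df / 2) - log(prior_df / 2))
        } else exp(mean(e))
      }
    }
  }
  if (prior_df < 0 || prior_var <= 0) {
    stop("prior df must be >= 0 and prior variance > 0", call. = FALSE)
  }

  var_post <- if (is.infinite(prior_df)) {
    rep(prior_var, length(s2))
  } else {
    (prior_df * prior_var + d * s2) / (prior_df + d)
  }
  # cap total df at the pooled residual df across all genes
  df_total <- min(prior_df + d, d * length(s2))

  tt <- fits$coefficients / (fits$stdev_unscaled * sqrt(var_post))
  pp <- 2 * stats::pt(-abs(tt), df = df_total)
  adj <- pp
  for (j in seq_len(ncol(pp))) adj[, j] <- adjust_bh(pp[, j])

  q <- ncol(fits$coefficients) - 1
  if (q >= 1) {
    Fstat <- ((fits$rss0 - fits$rss) / q) / var_post
    Fp <- stats::pf(Fstat, q, df_total, lower.tail = FALSE)
    Fadj <- adjust_bh(Fp)
  } else {
    Fstat <- Fp <- Fadj <- rep(NA_real_, length(s2))
  }

  structure(list(df_prior = prior_df, var_prior = prior_var,
                 var_post = var_post, df_residual = d, df_total = df_total,
                 coefficients = fits$coefficients, t = tt, p = pp,
                 adj_p = adj, F = Fstat, F_p = Fp, F_adj_p = Fadj,
                 F_df1 = q, kind = fits$kind, genes = fits$genes),
            class = "moderated_stats")
}

#' @export
print.moderated_stats <- function(x, ...) {
  cat("<moderated_stats> ", length(x$genes), " genes; prior df ",
      signif(x$df_prior, 4), ", prior variance ", signif(x$var_prior, 4),
      "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, capped at 1 and monotone in p-rank.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Regulation status of a gene across stages
#'
#' `UP` if the stage log fold-changes versus control are all positive,
#' `DOWN` if all negative, `MIXED` otherwise.
#'
#' @param stage_lfcs Numeric vector of four stage lfcs, or a genes x 4
#'   matrix.
#' @return Character scalar or vector in `UP`, `DOWN`, `MIXED`.
#' @export
regulation_status <- function(stage_lfcs) {
  m <- if (is.matrix(stage_lfcs)) stage_lfcs else
    matrix(stage_lfcs, nrow = 1)
  if (ncol(m) != 4) stop("expected four stage lfc values", call. = FALSE)
  out <- ifelse(rowSums(m > 0) == 4, "UP",
                ifelse(rowSums(m < 0) == 4, "DOWN", "MIXED"))
  if (!is.matrix(stage_lfcs)) out[1] else unname(out)
}
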