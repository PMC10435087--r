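#' Quasi-Poisson regression of per-gene mutation counts
#'
#' Fits the log-linear mean model `log mu = X beta` to non-negative counts
#' by iteratively reweighted least squares on the Poisson score equations,
#' then estimates the quasi-likelihood dispersion as the Pearson chi-square
#' divided by the residual degrees of freedom and inflates every standard
#' error by its square root. This is the model used to relate per-gene (or
#' per-gene CDS) mutation counts to sequence length, expression and GC
#' content; covariates enter on their raw scales (length in nucleotides,
#' expression in RPKM, GC as percent). Rows with any missing covariate or
#' response are dropped before fitting.
#'
#' @param formula model formula, e.g.
#'   `mutations ~ gene_length + expression + gc_percent`.
#' @param data data frame holding the response (counts) and covariates.
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @param maxit iteration cap (default 100).
#' @return object of class `mutability_fit` with coefficients, scaled
#'   standard errors, `dispersion` (Pearson chi-square / df), covariate
#'   IQRs and means, fitted values and residual df. A dispersion of zero
#'   (perfect fit) is flagged `degenerate`.
#' @seealso [iqr_rate_ratio()], [centered_rr_curve()].
#' @examples
#' d <- data.frame(y = rpois(500, 2), x = rnorm(500))
#' fit <- fit_mutability(y ~ x, d)
#' summary(fit)
#' @export
fit_mutability <- function(formula, data, tol = 1e-8, maxit = 100L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(y < 0) || any(y != round(y)))
    stop("response must be non-negative integer counts")
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more parameters than observations")
  if (qr(X)$rank < p)
    stop("rank-deficient design matrix (collinear covariates)")

  # IRLS for the Poisson log link
  mu <- pmax(y, 0.5)
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- mu
    z <- eta + (y - mu) / mu
    wls <- stats::lm.wfit(X, z, w)
    beta_new <- wls$coefficients
    if (anyNA(beta_new)) stop("separation or rank deficiency during IRLS")
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta)
    if (any(eta > 700)) stop("diverging linear predictor (separation?)")
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("IRLS did not converge within ", maxit, " iterations")

  df_res <- n - p
  pearson <- sum((y - mu)^2 / mu)
  phi <- pearson / df_res
  degenerate <- phi == 0
  if (degenerate)
    warning("zero Pearson dispersion: perfect fit (degenerate data)")
  XtWX <- crossprod(X * sqrt(mu))
  cov_unscaled <- chol2inv(chol(XtWX))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  se_unscaled <- sqrt(diag(cov_unscaled))
  se <- se_unscaled * sqrt(phi)

  covars <- setdiff(colnames(X), "(Intercept)")
  iqr <- vapply(covars, function(v) stats::IQR(X[, v]), numeric(1))
  xbar <- vapply(covars, function(v) mean(X[, v]), numeric(1))

  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    se_unscaled = stats::setNames(se_unscaled, colnames(X)),
    vcov = cov_unscaled * phi,
    dispersion = phi, pearson = pearson,
    fitted.values = mu, y = y, X = X,
    n = n, df.residual = df_res,
    iterations = it, converged = converged, degenerate = degenerate,
    iqr = iqr, xbar = xbar,
    terms = attr(mf, "terms"), formula = formula, call = match.call()
  ), class = "mutability_fit")
}

#' @export
coef.mutability_fit <- function(object, ...) object$coefficients

#' @export
vcov.mutability_fit <- function(object, ...) object$vcov

#' @export
fitted.mutability_fit <- function(object, ...) object$fitted.values

#' @export
print.mutability_fit <- function(x, ...) {
  cat("Quasi-Poisson mutability model:",
      deparse(x$formula), "\n")
  cat(sprintf("  n = %d, dispersion = %.4g, %d IRLS iterations\n",
              x$n, x$dispersion, x$iterations))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.mutability_fit <- function(object, ...) {
  est <- object$coefficients
  se <- object$se
  tval <- est / se
  pval <- 2 * stats::pt(-abs(tval), df = object$df.residual)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, dispersion = object$dispersion,
              n = object$n, df.residual = object$df.residual,
              formula = object$formula,
              rate_ratios = tryCatch(iqr_rate_ratio(object),
                                     warning = function(w) NULL))
  class(out) <- "summary.mutability_fit"
  out
}

#' @export
print.summary.mutability_fit <- function(x, ...) {
  cat("Quasi-Poisson mutability model:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, residual df = %d, dispersion = %.4g\n\n",
              x$n, x$df.residual, x$dispersion))
  stats::printCoefmat(x$coefficients, digits = 4)
  if (!is.null(x$rate_ratios)) {
    cat("\nRate ratios per IQR increase (95% CI):\n")
    rr <- x$rate_ratios
    for (i in seq_len(nrow(rr)))
      cat(sprintf("  %-16s RR = %.3f [%.3f, %.3f]\n",
                  rr$covariate[i], rr$rr[i], rr$lo[i], rr$hi[i]))
  }
  invisible(x)
}

#' @export
predict.mutability_fit <- function(object, newdata = NULL,
                                   type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- drop(object$X %*% object$coefficients)
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else exp(eta)
}

#' @export
residuals.mutability_fit <- function(object,
                                     type = c("pearson", "deviance",
                                              "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = sign(y - mu) *
           sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))))
}

#' Simulate count data from a fitted mutability model
#'
#' Draws Poisson counts at the fitted means. The quasi-likelihood fit does
#' not define a full distribution; the Poisson draw reproduces the mean
#' structure only, not any estimated overdispersion.
#' @param object a `mutability_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... ignored.
#' @return data frame with `nsim` columns.
#' @export
simulate.mutability_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim,
      stats::rpois(object$n, object$fitted.values)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Rate ratio per interquartile-range increase of a covariate
#'
#' Multiplies each coefficient by the covariate's IQR and exponentiates:
#' the multiplicative change in mutation rate per IQR increase, with a
#' Wald 95% CI on the log scale. A zero-IQR covariate is uninformative and
#' returns RR = 1 with a warning.
#'
#' @param fit a `mutability_fit`.
#' @param covariate covariate name(s); default all non-intercept terms.
#' @param level confidence level (default 0.95).
#' @return data frame with columns `covariate`, `beta`, `iqr`, `rr`, `lo`,
#'   `hi`.
#' @export
iqr_rate_ratio <- function(fit, covariate = NULL, level = 0.95) {
  covariate <- covariate %||% names(fit$iqr)
  if (any(!covariate %in% names(fit$iqr)))
    stop("unknown covariate(s): ",
         paste(setdiff(covariate, names(fit$iqr)), collapse = ", "))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(covariate, function(v) {
    b <- fit$coefficients[[v]]
    s <- fit$se[[v]]
    iqr <- fit$iqr[[v]]
    if (iqr == 0) {
      warning("covariate '", v, "' has zero IQR; RR fixed at 1")
      return(data.frame(covariate = v, beta = b, iqr = 0, rr = 1,
                        lo = 1, hi = 1))
    }
    data.frame(covariate = v, beta = b, iqr = iqr,
               rr = exp(b * iqr),
               lo = exp((b - z * s) * iqr),
               hi = exp((b + z * s) * iqr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Centered rate-ratio curve for one covariate
#'
#' Predicted mutation rate ratio of an observation with covariate value `x`
#' versus one at the covariate mean, other covariates held fixed:
#' `RR(x) = exp(beta * (x - xbar))`, with a pointwise Wald band from the
#' coefficient's standard error. `RR` equals 1 exactly at the mean.
#'
#' @param fit a `mutability_fit`.
#' @param covariate covariate name.
#' @param grid x values (default: 101 points over the observed range).
#' @param level confidence level (default 0.95).
#' @return data frame of class `rr_curve`: `x`, `rr`, `lo`, `hi`.
#' @export
centered_rr_curve <- function(fit, covariate, grid = NULL, level = 0.95) {
  if (!covariate %in% names(fit$iqr))
    stop("unknown covariate: ", covariate)
  xs <- fit$X[, covariate]
  grid <- grid %||% seq(min(xs), max(xs), length.out = 101L)
  b <- fit$coefficients[[covariate]]
  s <- fit$se[[covariate]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  d <- grid - fit$xbar[[covariate]]
  out <- data.frame(x = grid, rr = exp(b * d),
                    lo = exp((b - z * s) * d), hi = exp((b + z * s) * d))
  # the band is pointwise in |d|; keep lo <= hi on both sides of the mean
  swap <- out$lo > out$hi
  tmp <- out$lo[swap]; out$lo[swap] <- out$hi[swap]; out$hi[swap] <- tmp
  attr(out, "covariate") <- covariate
  class(out) <- c("rr_curve", "data.frame")
  out
}

#' @export
plot.rr_curve <- function(x, ...) {
  graphics::plot(x$x, x$rr, type = "n", ylim = range(x$lo, x$hi),
                 xlab = attr(x, "covariate"),
                 ylab = "centered rate ratio", ...)
  graphics::polygon(c(x$x, rev(x$x)), c(x$lo, rev(x$hi)),
                    col = "#33669933", border = NA)
  graphics::lines(x$x, x$rr, lwd = 2, col = "#336699")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Assemble the per-gene model frame for [fit_mutability()]
#'
#' Pools mutation counts over all subclones and exposure classes into one
#' response per gene, joining length, expression and GC (as percent) at
#' either gene or CDS level. Genes with missing covariates are retained
#' here and dropped by the fitter; at CDS level only genes with coding
#' sequence are included.
#'
#' @param counts a `mutation_counts` data frame.
#' @param genes a `gene_models` data frame.
#' @param level `"gene"` or `"cds"`.
#' @return data frame with columns `gene_id`, `mutations`, `length`,
#'   `expression`, `gc_percent`.
#' @export
mutability_data <- function(counts, genes, level = c("gene", "cds")) {
  level <- match.arg(level)
  keep <- if (level == "cds") genes$cds_length > 0L else rep(TRUE, nrow(genes))
  g <- genes[keep, , drop = FALSE]
  col <- if (level == "gene") "gene_count" else "cds_count"
  tot <- tapply(counts[[col]], counts$gene_id, sum)
  mut <- stats::setNames(integer(nrow(g)), g$gene_id)
  hit <- intersect(names(tot), g$gene_id)
  mut[hit] <- as.integer(tot[hit])
  data.frame(
    gene_id = g$gene_id,
    mutations = unname(mut),
    length = if (level == "gene") g$gene_length else g$cds_length,
    expression = g$expression,
    gc_percent = 100 * (if (level == "gene") g$gene_gc else g$cds_gc),
    stringsAsFactors = FALSE
  )
}
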