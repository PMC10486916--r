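#' Distribution specifications
#'
#' A `dist_spec` describes one stochastic model input: a family
#' (`lognormal`, `normal`, `triangular`, `uniform` or `fixed`), its
#' parameters, and an optional lower truncation bound. Lognormals are
#' parameterised by `(meanlog, sdlog)` of the underlying normal.
#'
#' @param meanlog,sdlog Lognormal parameters (sdlog > 0).
#' @param mean,sd Normal parameters (sd > 0).
#' @param min,mode,max Triangular parameters (min <= mode <= max) /
#'   uniform bounds (min < max).
#' @param value Fixed (degenerate) value.
#' @param truncate_low Optional lower bound; sampling is conditional on
#'   exceeding it.
#' @return An object of class `dist_spec`.
#' @examples
#' dist_triangular(180, 345, 365)
#' dist_fixed(2190)
#' @name dist_spec
NULL

new_dist_spec <- function(family, params, truncate_low = NULL) {
  structure(
    list(family = family, params = params, truncate_low = truncate_low),
    class = "dist_spec"
  )
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog, truncate_low = NULL) {
  if (!is.finite(meanlog) || !is.finite(sdlog) || sdlog <= 0) {
    abort("lognormal requires finite meanlog and sdlog > 0")
  }
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog),
                truncate_low)
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd, truncate_low = NULL) {
  if (!is.finite(mean) || !is.finite(sd) || sd <= 0) {
    abort("normal requires finite mean and sd > 0")
  }
  new_dist_spec("normal", list(mean = mean, sd = sd), truncate_low)
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(min, mode, max, truncate_low = NULL) {
  if (!(min <= mode && mode <= max) || min == max) {
    abort("triangular requires min <= mode <= max with min < max")
  }
  new_dist_spec("triangular", list(min = min, mode = mode, max = max),
                truncate_low)
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max, truncate_low = NULL) {
  if (!(min < max)) abort("uniform requires min < max")
  new_dist_spec("uniform", list(min = min, max = max), truncate_low)
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  if (!is.finite(value)) abort("fixed requires a finite value")
  new_dist_spec("fixed", list(value = value))
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  cat("<dist_spec> ", x$family, "(", p, ")", sep = "")
  if (!is.null(x$truncate_low)) cat(" truncated at >", x$truncate_low)
  cat("\n")
  invisible(x)
}

#' Fit a lognormal by matching moments
#'
#' Inverts the lognormal moment formulas so that the fitted distribution's
#' analytic mean and standard deviation equal the supplied values:
#' `sdlog^2 = log(1 + sd^2/mean^2)`,
#' `meanlog = log(mean^2 / sqrt(mean^2 + sd^2))`.
#' This is how concentration distributions are parameterised from reported
#' mean +/- SD summaries.
#'
#' @param mean,sd Target arithmetic mean and standard deviation (> 0).
#' @param truncate_low Optional lower truncation bound.
#' @return A lognormal [dist_spec].
#' @examples
#' sp <- fit_lognormal_moments(0.0379, 0.014)
#' dist_mean(sp)   # 0.0379
#' dist_sd(sp)     # 0.014
#' @export
fit_lognormal_moments <- function(mean, sd, truncate_low = NULL) {
  if (!is.finite(mean) || mean <= 0 || !is.finite(sd) || sd <= 0) {
    abort("moment fitting requires mean > 0 and sd > 0")
  }
  s2 <- log1p(sd^2 / mean^2)   # log1p: stable as sd -> 0
  dist_lognormal(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2),
                 truncate_low = truncate_low)
}

#' Analytic moments of a distribution spec
#'
#' Mean and standard deviation of the (untruncated) distribution.
#'
#' @param spec A [dist_spec].
#' @return A single number.
#' @export
dist_mean <- function(spec) {
  p <- spec$params
  switch(spec$family,
    lognormal  = exp(p$meanlog + p$sdlog^2 / 2),
    normal     = p$mean,
    triangular = (p$min + p$mode + p$max) / 3,
    uniform    = (p$min + p$max) / 2,
    fixed      = p$value,
    abort(paste0("unknown distribution family '", spec$family, "'"))
  )
}

#' @rdname dist_mean
#' @export
dist_sd <- function(spec) {
  p <- spec$params
  switch(spec$family,
    lognormal  = exp(p$meanlog + p$sdlog^2 / 2) * sqrt(exp(p$sdlog^2) - 1),
    normal     = p$sd,
    triangular = sqrt((p$min^2 + p$mode^2 + p$max^2 - p$min * p$mode -
                       p$min * p$max - p$mode * p$max) / 18),
    uniform    = (p$max - p$min) / sqrt(12),
    fixed      = 0,
    abort(paste0("unknown distribution family '", spec$family, "'"))
  )
}

# quantile function; the backbone of all sampling (inverse transform)
dist_quantile <- function(spec, prob) {
  p <- spec$params
  q <- switch(spec$family,
    lognormal  = qlnorm(prob, p$meanlog, p$sdlog),
    normal     = qnorm(prob, p$mean, p$sd),
    triangular = qtriangular(prob, p$min, p$mode, p$max),
    uniform    = qunif(prob, p$min, p$max),
    fixed      = rep(p$value, length(prob)),
    abort(paste0("unknown distribution family '", spec$family, "'"))
  )
  q
}

dist_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    lognormal  = plnorm(q, p$meanlog, p$sdlog),
    normal     = pnorm(q, p$mean, p$sd),
    triangular = ptriangular(q, p$min, p$mode, p$max),
    uniform    = punif(q, p$min, p$max),
    fixed      = as.numeric(q >= p$value),
    abort(paste0("unknown distribution family '", spec$family, "'"))
  )
}

# triangular distribution: closed-form CDF and inverse CDF
ptriangular <- function(q, min, mode, max) {
  out <- numeric(length(q))
  left <- q > min & q <= mode
  right <- q > mode & q < max
  out[left] <- (q[left] - min)^2 / ((max - min) * (mode - min))
  out[right] <- 1 - (max - q[right])^2 / ((max - min) * (max - mode))
  out[q >= max] <- 1
  out
}

qtriangular <- function(prob, min, mode, max) {
  fc <- (mode - min) / (max - min)
  ifelse(prob < fc,
         min + sqrt(prob * (max - min) * (mode - min)),
         max - sqrt((1 - prob) * (max - min) * (max - mode)))
}

# map uniforms into the truncated region [F(low), 1)
apply_truncation <- function(spec, u) {
  if (is.null(spec$truncate_low) || spec$family == "fixed") return(u)
  p_low <- dist_cdf(spec, spec$truncate_low)
  p_low + u * (1 - p_low)
}

#' Draw a seeded random sample from a distribution spec
#'
#' Sampling is by inverse transform, so a given seed and spec always
#' produce the identical vector. Lower truncation is honoured by
#' conditioning the uniforms on the truncated region, which preserves both
#' determinism and the conditional distribution.
#'
#' @param spec A [dist_spec].
#' @param n Sample size (>= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return Numeric vector of length `n`.
#' @examples
#' dist_sample(dist_uniform(1, 7), 5, seed = 1)
#' @export
dist_sample <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) abort("`n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (spec$family == "fixed") return(rep(spec$params$value, n))
  u <- apply_truncation(spec, runif(n))
  dist_quantile(spec, u)
}

#' Convert a Spearman correlation to the Gaussian-copula Pearson scale
#'
#' Uses the exact relation for bivariate normals,
#' `rho = 2 * sin(pi * r_s / 6)`, applied elementwise.
#'
#' @param r_s Spearman rank correlation(s) in `[-1, 1]`.
#' @return Pearson correlation(s) on the latent Gaussian scale.
#' @export
spearman_to_pearson <- function(r_s) 2 * sin(pi * r_s / 6)

#' Correlated sampling through a Gaussian copula
#'
#' Draws an `n x k` sample whose marginals follow the supplied specs and
#' whose Spearman rank-correlation matrix converges to `spearman_target`.
#' The target is converted to the latent Pearson scale with
#' `2 * sin(pi * r/6)`; latent normals are drawn with that correlation and
#' pushed through each marginal's quantile function.
#'
#' @param specs A list of [dist_spec] objects (length k); names become
#'   column names.
#' @param spearman_target Symmetric k x k matrix with unit diagonal. Must be
#'   positive semi-definite after conversion to the Gaussian scale unless
#'   `repair = TRUE`.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @param repair If `TRUE`, a non-PSD converted matrix is repaired by
#'   clipping negative eigenvalues and rescaling to unit diagonal. Never
#'   applied silently: the repaired matrix is attached as attribute
#'   `"gauss_correlation"`.
#' @return An `n x k` numeric matrix.
#' @export
sample_correlated <- function(specs, spearman_target, n, seed = NULL,
                              repair = FALSE) {
  k <- length(specs)
  stopifnot(k >= 1, all(vapply(specs, inherits, logical(1), "dist_spec")))
  if (k == 1) {
    out <- matrix(dist_sample(specs[[1]], n, seed = seed), ncol = 1)
    colnames(out) <- names(specs)
    return(out)
  }
  spearman_target <- as.matrix(spearman_target)
  if (!isTRUE(all.equal(spearman_target, t(spearman_target),
                        tolerance = 1e-10))) {
    abort("`spearman_target` must be symmetric")
  }
  if (!isTRUE(all.equal(unname(diag(spearman_target)), rep(1, k)))) {
    abort("`spearman_target` must have a unit diagonal")
  }
  rho <- spearman_to_pearson(spearman_target)
  diag(rho) <- 1
  ev <- eigen(rho, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    if (!repair) {
      abort(paste0(
        "target correlation is not positive semi-definite on the Gaussian ",
        "scale (min eigenvalue ", signif(min(ev$values), 3), "); ",
        "set repair = TRUE to clip eigenvalues to the nearest valid matrix"
      ))
    }
    rho <- nearest_psd_correlation(rho)
    ev <- eigen(rho, symmetric = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  # square root of rho via eigen decomposition (tolerates semi-definiteness)
  root <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  z <- matrix(rnorm(n * k), nrow = n) %*% t(root)
  u <- pnorm(z)
  out <- vapply(seq_len(k), function(j) {
    dist_quantile(specs[[j]], apply_truncation(specs[[j]], u[, j]))
  }, numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- names(specs)
  attr(out, "gauss_correlation") <- rho
  out
}

# eigenvalue clipping followed by rescaling to a unit diagonal
nearest_psd_correlation <- function(m, eps = 1e-8) {
  ev <- eigen(m, symmetric = TRUE)
  fixed <- ev$vectors %*% diag(pmax(ev$values, eps)) %*% t(ev$vectors)
  d <- sqrt(diag(fixed))
  out <- fixed / tcrossprod(d)
  diag(out) <- 1
  out
}
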