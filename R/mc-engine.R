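#' Pooled default concentration distributions
#'
#' Lognormal specs moment-fitted to the pooled mean +/- SD of each element
#' across all bean samples (mg/kg): As 0.0349 +/- 0.019, Cd 0.0379 +/-
#' 0.014, Cr 0.246 +/- 0.123, Hg 0.0019 +/- 0.0017, Pb 0.0246 +/- 0.011.
#' These are the concentration inputs of the default risk runs.
#'
#' @return A named list of lognormal [dist_spec] objects.
#' @export
pooled_concentration_specs <- function() {
  stats <- pooled_concentration_stats()
  setNames(
    purrr::map2(stats$mean, stats$sd, fit_lognormal_moments),
    stats$element
  )
}

#' @rdname pooled_concentration_specs
#' @export
pooled_concentration_stats <- function() {
  tibble(
    element = .elements,
    mean = c(0.0349, 0.0379, 0.246, 0.0019, 0.0246),
    sd   = c(0.019, 0.014, 0.123, 0.0017, 0.011)
  )
}

#' Fit concentration distributions from prepared records
#'
#' Moment-fits a pooled lognormal per element from substituted
#' concentration records, for feeding into [run_simulation()].
#'
#' @param records Substituted concentration records.
#' @return A named list of lognormal [dist_spec] objects.
#' @export
fit_concentration_specs <- function(records) {
  st <- records |>
    filter(!is.na(.data$value)) |>
    group_by(.data$element) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
              .groups = "drop")
  setNames(purrr::map2(st$mean, st$sd, fit_lognormal_moments), st$element)
}

#' Run the Monte Carlo risk simulation
#'
#' Propagates the stochastic exposure inputs through the EDI/THQ/HI/CR
#' equations. Each iteration independently draws one concentration per
#' element (lognormal by default), an exposure frequency EF (triangular),
#' an exposure duration ED (uniform) and a body weight BW (normal,
#' truncated at > 0); the ingestion rate IR and averaging time AT are
#' fixed per population. Per element the iteration computes the estimated
#' daily intake and the target hazard quotient; the hazard index is the
#' row sum of the THQs; carcinogenic risk is computed for elements with a
#' slope factor (As), always using the inorganic fraction `f`.
#'
#' By default the THQ pathway uses the *total* measured concentration
#' (`inorganic_as_in_thq = FALSE`); set it to `TRUE` to apply the
#' inorganic-As fraction to the non-carcinogenic pathway as well (see the
#' methods vignette for why total As is the default).
#'
#' @param conc_specs Named list of [dist_spec] concentration distributions,
#'   one per element in `tox$symbol` (mg/kg).
#' @param population Population group name (`"children"`, `"teens"`,
#'   `"adults"`) or a one-row parameter table as from
#'   [default_populations()].
#' @param tox Toxicology table ([default_element_tox()]).
#' @param n_iter Number of iterations (>= 1; >= 1000 recommended — a
#'   warning is raised below that).
#' @param seed Integer seed; a fixed seed makes the run bit-reproducible.
#' @param inorganic_as_in_thq Apply the toxic fraction `f` in the THQ
#'   pathway too (default `FALSE`).
#' @param conc_spearman Optional element-by-element Spearman target matrix
#'   for correlated concentration draws (via [sample_correlated()]);
#'   `NULL` (default) draws elements independently.
#' @param exposure_specs Optional named list overriding the
#'   population-derived exposure distributions; recognised names are
#'   `"ef"`, `"ed"`, `"bw"`, each a [dist_spec]. Useful for degenerate
#'   (all-fixed) reductions to the deterministic equations.
#' @return A `risk_distribution` object with fields `population`
#'   (parameter row), `n_iter`, `seed`, `elements`, `thq` (n_iter x element
#'   matrix), `hi` (vector), `cr` (n_iter x carcinogen matrix), `inputs`
#'   (tibble of retained input draws for sensitivity analysis) and `meta`.
#' @examples
#' rd <- run_simulation(pooled_concentration_specs(), "adults",
#'                      n_iter = 2000, seed = 1)
#' glance(rd)
#' @export
run_simulation <- function(conc_specs, population,
                           tox = default_element_tox(),
                           n_iter = 10000, seed = NULL,
                           inorganic_as_in_thq = FALSE,
                           conc_spearman = NULL, exposure_specs = list()) {
  validate_element_tox(tox)
  pop <- resolve_population(population)
  elements <- tox$symbol
  missing_specs <- setdiff(elements, names(conc_specs))
  if (length(missing_specs) > 0) {
    abort(paste0("no concentration spec for element(s): ",
                 paste(missing_specs, collapse = ", ")))
  }
  if (!is.numeric(n_iter) || n_iter < 1) abort("`n_iter` must be >= 1")
  if (n_iter < 1000) {
    warn("n_iter < 1000 gives unstable percentile estimates")
  }
  if (!is.null(seed)) set.seed(seed)

  # fixed draw order for seed determinism: concentrations, EF, ED, BW
  if (is.null(conc_spearman)) {
    conc <- vapply(elements, function(el) dist_sample(conc_specs[[el]], n_iter),
                   numeric(n_iter))
  } else {
    conc <- sample_correlated(conc_specs[elements], conc_spearman, n_iter)
  }
  conc <- matrix(conc, nrow = n_iter, dimnames = list(NULL, elements))
  ef_spec <- exposure_specs$ef %||%
    dist_triangular(pop$ef_min, pop$ef_mode, pop$ef_max)
  ed_spec <- exposure_specs$ed %||% dist_uniform(pop$ed_min, pop$ed_max)
  bw_spec <- exposure_specs$bw %||%
    dist_normal(pop$bw_mean, pop$bw_sd, truncate_low = 0)
  ef <- dist_sample(ef_spec, n_iter)
  ed <- dist_sample(ed_spec, n_iter)
  bw <- dist_sample(bw_spec, n_iter)

  f <- setNames(tox$f, tox$symbol)
  rfd <- setNames(tox$rfd, tox$symbol)
  sf <- setNames(tox$sf, tox$symbol)

  thq_m <- vapply(elements, function(el) {
    f_thq <- if (inorganic_as_in_thq) f[[el]] else 1
    e <- edi(conc[, el], ef = ef, ed = ed, ir = pop$ir, bw = bw, at = pop$at,
             f = f_thq)
    thq(e, rfd[[el]], element = el)
  }, numeric(n_iter))
  thq_m <- matrix(thq_m, nrow = n_iter, dimnames = list(NULL, elements))
  hi <- rowSums(thq_m)

  carcinogens <- elements[!is.na(sf)]
  cr_m <- vapply(carcinogens, function(el) {
    e <- edi(conc[, el], ef = ef, ed = ed, ir = pop$ir, bw = bw, at = pop$at,
             f = f[[el]])
    carcinogenic_risk(e, sf[[el]], element = el)
  }, numeric(n_iter))
  cr_m <- matrix(cr_m, nrow = n_iter, dimnames = list(NULL, carcinogens))

  inputs <- as_tibble(conc) |>
    rlang::set_names(paste0("C_", elements)) |>
    mutate(EF = ef, ED = ed, BW = bw)

  structure(
    list(
      population = pop,
      n_iter = as.integer(n_iter),
      seed = seed,
      elements = elements,
      thq = thq_m,
      hi = hi,
      cr = cr_m,
      inputs = inputs,
      meta = list(
        inorganic_as_in_thq = inorganic_as_in_thq,
        correlated_concentrations = !is.null(conc_spearman),
        # AT is fixed while ED is random, so EF*ED can exceed AT
        ef_ed_exceeds_at_frac = mean(ef * ed > pop$at)
      )
    ),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat("<risk_distribution> ", x$population$population, ", ",
      format(x$n_iter, big.mark = ","), " iterations",
      if (!is.null(x$seed)) paste0(", seed ", x$seed), "\n", sep = "")
  cat("  HI: mean ", signif(mean(x$hi), 3),
      ", P50 ", signif(median(x$hi), 3),
      ", P(HI > 1) ", signif(100 * mean(x$hi > 1), 3), "%\n", sep = "")
  if (ncol(x$cr) > 0) {
    cat("  CR(", colnames(x$cr)[1], "): mean ",
        signif(mean(x$cr[, 1]), 3), "\n", sep = "")
  }
  invisible(x)
}

# draws for one named output: "HI", "THQ-<element>" or "CR-<element>"
output_draws <- function(dist, output) {
  if (identical(output, "HI")) return(dist$hi)
  if (grepl("^CR-", output)) {
    el <- sub("^CR-", "", output)
    if (!el %in% colnames(dist$cr)) {
      abort(paste0("no carcinogenic-risk draws for '", el, "'"))
    }
    return(dist$cr[, el])
  }
  el <- sub("^THQ-", "", output)
  if (el %in% colnames(dist$thq)) return(dist$thq[, el])
  abort(paste0("unknown output '", output,
               "'; use 'HI', 'THQ-<element>' or 'CR-<element>'"))
}

#' Percentiles and means of the risk outputs
#'
#' Empirical quantiles (type-7 convention) and means of every THQ, the
#' hazard index and each carcinogenic risk.
#'
#' @param dist A `risk_distribution`.
#' @param probs Probabilities in (0, 1); default the reported 0.50, 0.70,
#'   0.95.
#' @return A tidy tibble with columns `population`, `output`, `statistic`
#'   (`"mean"`, `"P50"`, ...), `value`.
#' @export
risk_percentiles <- function(dist, probs = c(0.5, 0.7, 0.95)) {
  if (any(probs <= 0 | probs >= 1)) abort("`probs` must lie in (0, 1)")
  outputs <- c(paste0("THQ-", colnames(dist$thq)), "HI",
               if (ncol(dist$cr) > 0) paste0("CR-", colnames(dist$cr)))
  purrr::map(outputs, function(o) {
    d <- output_draws(dist, o)
    tibble(
      population = dist$population$population,
      output = o,
      statistic = c("mean", paste0("P", round(100 * probs))),
      value = c(mean(d), quantile(d, probs, names = FALSE))
    )
  }) |> purrr::list_rbind()
}

#' Exceedance probability of a risk output
#'
#' Percentage of Monte Carlo iterations in which an output exceeds a
#' threshold, with the binomial Monte Carlo standard error.
#'
#' @param dist A `risk_distribution`.
#' @param output `"HI"` (default), `"THQ-<element>"` or `"CR-<element>"`.
#' @param threshold Exceedance threshold (default 1, the HI benchmark).
#' @return A one-row tibble: `population`, `output`, `threshold`,
#'   `percent`, `se` (both in percentage points), `n_iter`.
#' @examples
#' rd <- run_simulation(pooled_concentration_specs(), "children",
#'                      n_iter = 2000, seed = 1)
#' exceedance(rd, "HI", 1)
#' @export
exceedance <- function(dist, output = "HI", threshold = 1) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  d <- output_draws(dist, output)
  p <- mean(d > threshold)
  tibble(
    population = dist$population$population,
    output = output,
    threshold = threshold,
    percent = 100 * p,
    se = 100 * sqrt(p * (1 - p) / length(d)),
    n_iter = length(d)
  )
}

#' Iteration-ladder convergence check
#'
#' Re-runs the simulation at each rung of an ascending iteration ladder
#' and reports the P50, P95 and mean of the hazard index per rung, the
#' maximum relative drift of those statistics between successive rungs,
#' and a stability flag (drift < `stable_tol`).
#'
#' @inheritParams run_simulation
#' @param iteration_ladder Ascending iteration counts; default
#'   `c(5000, 10000, 50000)`.
#' @param stable_tol Relative-drift threshold for the `stable` flag
#'   (default 0.02).
#' @return A list with `rungs` (tibble: n_iter, p50, p95, mean, and the
#'   drift relative to the previous rung), `max_drift` (NA for a
#'   single-rung ladder) and `stable`.
#' @export
convergence_check <- function(conc_specs, population,
                              tox = default_element_tox(),
                              iteration_ladder = c(5000, 10000, 50000),
                              seed = NULL, stable_tol = 0.02, ...) {
  if (is.unsorted(iteration_ladder, strictly = TRUE)) {
    abort("`iteration_ladder` must be strictly ascending")
  }
  rungs <- purrr::imap(iteration_ladder, function(n, i) {
    rd <- run_simulation(conc_specs, population, tox, n_iter = n,
                         seed = if (is.null(seed)) NULL else seed + i - 1, ...)
    tibble(n_iter = n, p50 = median(rd$hi),
           p95 = quantile(rd$hi, 0.95, names = FALSE), mean = mean(rd$hi))
  }) |> purrr::list_rbind()
  stat <- as.matrix(rungs[c("p50", "p95", "mean")])
  drift <- rep(NA_real_, nrow(stat))
  if (nrow(stat) > 1) {
    for (i in 2:nrow(stat)) {
      denom <- ifelse(stat[i - 1, ] == 0, 1, abs(stat[i - 1, ]))
      drift[i] <- max(abs(stat[i, ] - stat[i - 1, ]) / denom)
    }
  }
  rungs$drift <- drift
  max_drift <- if (all(is.na(drift))) NA_real_ else max(drift, na.rm = TRUE)
  list(rungs = rungs, max_drift = max_drift,
       stable = isTRUE(max_drift < stable_tol))
}

#' Contribution-to-variance sensitivity analysis
#'
#' Apportions the variability of a risk output among the stochastic inputs
#' using the rank-correlation convention popularised by spreadsheet Monte
#' Carlo tools: each input's share is its squared Spearman correlation
#' with the output, normalised so the shares sum to 100%. The signed rank
#' correlations are reported alongside. Constant (degenerate) inputs get
#' share 0 with a note.
#'
#' @param dist A `risk_distribution` (input draws are retained by
#'   [run_simulation()]).
#' @param output Output to decompose; default `"HI"`.
#' @return A `sensitivity_report`: tibble with columns `input`, `rho`
#'   (signed Spearman), `share` (percent), `note`, carrying the output
#'   name and method as attributes. Shares sum to 100.
#' @examples
#' rd <- run_simulation(pooled_concentration_specs(), "children",
#'                      n_iter = 2000, seed = 1)
#' sensitivity(rd)
#' @export
sensitivity <- function(dist, output = "HI") {
  y <- output_draws(dist, output)
  x <- dist$inputs
  rho <- vapply(x, function(v) {
    if (sd(v) == 0 || sd(y) == 0) NA_real_
    else cor(v, y, method = "spearman")
  }, numeric(1))
  r2 <- ifelse(is.na(rho), 0, rho^2)
  total <- sum(r2)
  share <- if (total > 0) 100 * r2 / total else r2
  out <- tibble(
    input = names(rho),
    rho = unname(rho),
    share = unname(share),
    note = ifelse(is.na(rho), "constant input; share set to 0", "")
  ) |>
    arrange(dplyr::desc(.data$share))
  structure(out, class = c("sensitivity_report", class(out)),
            output = output, method = "normalized-squared-spearman",
            population = dist$population$population)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Contribution to variance of", attr(x, "output"),
      "(", attr(x, "method"), ")\n")
  NextMethod()
}

#' @export
tidy.risk_distribution <- function(x, probs = c(0.5, 0.7, 0.95), ...) {
  risk_percentiles(x, probs = probs)
}

#' @export
glance.risk_distribution <- function(x, ...) {
  tibble(
    population = x$population$population,
    n_iter = x$n_iter,
    seed = x$seed %||% NA_integer_,
    hi_mean = mean(x$hi),
    hi_p50 = median(x$hi),
    hi_p95 = quantile(x$hi, 0.95, names = FALSE),
    pct_hi_gt_1 = 100 * mean(x$hi > 1),
    cr_as_mean = if ("As" %in% colnames(x$cr)) mean(x$cr[, "As"]) else NA_real_,
    pct_cr_as_gt_1e4 = if ("As" %in% colnames(x$cr))
      100 * mean(x$cr[, "As"] > 1e-4) else NA_real_
  )
}

#' @export
tidy.sensitivity_report <- function(x, ...) as_tibble(x)

#' Plot methods
#'
#' `autoplot.risk_distribution()` draws the cumulative distribution of the
#' hazard index (or another output); `autoplot.sensitivity_report()` a
#' contribution-to-variance bar chart.
#'
#' @param object The fitted object.
#' @param output Output name for the risk curve (default `"HI"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.risk_distribution <- function(object, output = "HI", ...) {
  d <- tibble(value = output_draws(object, output))
  ggplot(d, aes(x = .data$value)) +
    stat_ecdf(linewidth = 0.7) +
    labs(
      x = output, y = "Cumulative probability",
      title = paste0("Cumulative distribution of ", output, " (",
                     object$population$population, ")")
    ) +
    theme_minimal()
}

#' @rdname autoplot.risk_distribution
#' @export
autoplot.sensitivity_report <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$share,
                y = stats::reorder(.data$input, .data$share))) +
    geom_col(fill = "steelblue") +
    labs(
      x = "Contribution to variance (%)", y = NULL,
      title = paste("Sensitivity of", attr(object, "output"))
    ) +
    theme_minimal()
}
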