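#' Default per-bean-type marginal concentration parameters
#'
#' Mean concentration per (bean type, element) from the surveyed per-type
#' means, with the per-type SD taken as the pooled SD scaled by the ratio
#' of the type mean to the pooled mean (the survey's per-type SD column is
#' unreliable, so the pooled coefficient structure is reused instead).
#'
#' @return A tibble with columns `bean_type`, `element`, `mean`, `sd`.
#' @export
default_marginals <- function() {
  means <- tibble::tribble(
    ~bean_type,     ~As,     ~Cd,    ~Cr,      ~Hg,     ~Pb,
    "black bean",  0.0601,  0.0481, 0.322,  0.0019,   0.0253,
    "broad bean",  0.0197,  0.0159, 0.180,  0.00146,  0.0188,
    "mung bean",   0.0137,  0.0274, 0.101,  0.000632, 0.0302,
    "soybean",     0.0133,  0.0498, 0.267,  0.00213,  0.0267,
    "red bean",    0.0138,  0.0301, 0.164,  0.0012,   0.0308,
    "kidney bean", 0.0064,  0.0364, 0.222,  0.00258,  0.0498,
    "pea",         0.0139,  0.0223, 0.152,  0.00274,  0.0145
  )
  pooled <- pooled_concentration_stats()
  means |>
    tidyr::pivot_longer(-"bean_type", names_to = "element",
                        values_to = "mean") |>
    left_join(pooled, by = "element", suffix = c("", "_pooled")) |>
    mutate(sd = .data$sd * .data$mean / .data$mean_pooled) |>
    select("bean_type", "element", "mean", "sd")
}

#' Default planted Spearman targets
#'
#' Per-bean-type 5 x 5 Spearman target matrices planting the reported
#' correlated pairs: Cd-Pb 0.934 and Cd-Hg 0.746 in kidney beans, Cd-As
#' 0.720 in black beans, Pb-As 0.701 in red beans, Cd-Pb 0.792 in mung
#' beans, with the pooled-level Cd-Pb 0.399 and Cd-As 0.524 as the
#' baseline for every type not carrying a type-specific value; all other
#' pairs are 0. Matrices that are infeasible on the Gaussian-copula scale
#' (the kidney-bean trio is) are repaired by eigenvalue clipping, so the
#' planted values there are approximate by construction.
#'
#' @return A named list of 5 x 5 matrices, one per bean type.
#' @export
default_spearman_targets <- function() {
  base <- diag(5)
  dimnames(base) <- list(.elements, .elements)
  set_pair <- function(m, a, b, r) {
    m[a, b] <- r; m[b, a] <- r; m
  }
  pooled_base <- base |>
    set_pair("Cd", "Pb", 0.399) |>
    set_pair("Cd", "As", 0.524)
  targets <- setNames(rep(list(pooled_base), length(.bean_types)),
                      .bean_types)
  targets[["kidney bean"]] <- pooled_base |>
    set_pair("Cd", "Pb", 0.934) |>
    set_pair("Cd", "Hg", 0.746)
  targets[["black bean"]] <- set_pair(pooled_base, "Cd", "As", 0.720)
  targets[["red bean"]] <- set_pair(pooled_base, "Pb", "As", 0.701)
  targets[["mung bean"]] <- set_pair(pooled_base, "Cd", "Pb", 0.792)
  targets
}

#' Synthetic-data generator scenario
#'
#' Bundles everything the generator needs: per-bean-type sample counts
#' (defaults follow the survey design, 692 samples in total), per-type
#' lognormal marginals, per-type Spearman targets, per-element limits of
#' detection (values drawn below the LOD become non-detects), sampling
#' probabilities over the 11 areas, and the seed.
#'
#' @param bean_type_counts Named integer vector of samples per bean type.
#' @param marginals Tibble as from [default_marginals()].
#' @param spearman_targets Named list of matrices as from
#'   [default_spearman_targets()].
#' @param lods Named numeric vector of LODs per element (mg/kg); defaults
#'   to the assay LOQs divided by 3.3.
#' @param area_weights Named sampling probabilities over areas (uniform by
#'   default).
#' @param seed Integer seed.
#' @return A `generator_scenario` object.
#' @export
generator_scenario <- function(bean_type_counts = NULL, marginals = NULL,
                               spearman_targets = NULL, lods = NULL,
                               area_weights = NULL, seed = 20230902) {
  bean_type_counts <- bean_type_counts %||% c(
    "black bean" = 307, "broad bean" = 88, "mung bean" = 43,
    "soybean" = 104, "red bean" = 51, "kidney bean" = 12, "pea" = 87
  )
  marginals <- marginals %||% default_marginals()
  spearman_targets <- spearman_targets %||% default_spearman_targets()
  tox <- default_element_tox()
  lods <- lods %||% setNames(tox$lod, tox$symbol)
  area_weights <- area_weights %||%
    setNames(rep(1 / length(.areas), length(.areas)), .areas)

  if (any(bean_type_counts < 1)) abort("bean-type counts must be >= 1")
  if (any(marginals$mean <= 0) || any(marginals$sd <= 0)) {
    abort("marginal means and SDs must be > 0")
  }
  if (any(lods < 0)) abort("LODs must be >= 0")
  missing_marg <- setdiff(names(bean_type_counts),
                          unique(marginals$bean_type))
  if (length(missing_marg) > 0) {
    abort(paste0("no marginals for bean type(s): ",
                 paste(missing_marg, collapse = ", ")))
  }
  structure(
    list(bean_type_counts = bean_type_counts, marginals = marginals,
         spearman_targets = spearman_targets, lods = lods,
         area_weights = area_weights, seed = seed),
    class = "generator_scenario"
  )
}

#' @export
print.generator_scenario <- function(x, ...) {
  cat("<generator_scenario> ", sum(x$bean_type_counts), " samples across ",
      length(x$bean_type_counts), " bean types, ",
      length(x$area_weights), " areas, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate synthetic censored concentration records
#'
#' For each bean type, draws correlated lognormal 5-element concentration
#' vectors through the Gaussian copula (the per-type Spearman target is
#' PSD-repaired on the copula scale when required), assigns sampling areas
#' multinomially, then applies value-threshold censoring: any draw below
#' its element's LOD becomes a non-detect carrying that LOD (censoring
#' masks values, it never removes records). Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario A [generator_scenario()].
#' @return A concentration-record tibble (one row per sample x element,
#'   `sum(counts) * n_elements` rows).
#' @examples
#' sc <- generator_scenario(bean_type_counts = c("pea" = 20), seed = 1)
#' generate_samples(sc)
#' @export
generate_samples <- function(scenario) {
  stopifnot(inherits(scenario, "generator_scenario"))
  set.seed(scenario$seed)
  types <- names(scenario$bean_type_counts)
  recs <- purrr::map(types, function(bt) {
    n <- scenario$bean_type_counts[[bt]]
    marg <- scenario$marginals |>
      filter(.data$bean_type == bt) |>
      arrange(match(.data$element, .elements))
    specs <- setNames(
      purrr::map2(marg$mean, marg$sd, fit_lognormal_moments),
      marg$element
    )
    target <- scenario$spearman_targets[[bt]] %||% diag(length(specs))
    target <- target[marg$element, marg$element]
    vals <- sample_correlated(specs, target, n, repair = TRUE)
    areas <- sample(names(scenario$area_weights), n, replace = TRUE,
                    prob = scenario$area_weights)
    ids <- sprintf("%s-%04d", gsub("\\s+", "_", bt), seq_len(n))
    as_tibble(vals) |>
      mutate(sample_id = ids, area = areas, bean_type = bt) |>
      tidyr::pivot_longer(dplyr::all_of(marg$element),
                          names_to = "element", values_to = "value")
  }) |> purrr::list_rbind()
  recs |>
    mutate(
      lod = unname(scenario$lods[.data$element]),
      censored = .data$value < .data$lod,
      value = ifelse(.data$censored, NA_real_, .data$value)
    ) |>
    select("sample_id", "area", "bean_type", "element",
           "value", "censored", "lod")
}

#' Recover generator parameters from records
#'
#' Closes the parameter-recovery loop: from (substituted) records, moment-
#' fits a lognormal per (bean type, element) and recomputes the per-type
#' Spearman matrices, packaged for comparison against the generating
#' scenario.
#'
#' @param records Concentration records, typically
#'   `generate_samples() |> substitute_nondetects()`.
#' @return A list with `marginals` (tibble: bean_type, element, mean, sd,
#'   meanlog, sdlog) and `spearman` (tidy per-type correlation tibble as
#'   from [spearman_matrix()]).
#' @export
recover_parameters <- function(records) {
  marg <- records |>
    filter(!is.na(.data$value)) |>
    group_by(.data$bean_type, .data$element) |>
    summarise(mean = mean(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else 0,
              .groups = "drop") |>
    mutate(
      meanlog = ifelse(.data$sd > 0,
                       log(.data$mean) - log(1 + .data$sd^2 / .data$mean^2) / 2,
                       log(.data$mean)),
      sdlog = ifelse(.data$sd > 0,
                     sqrt(log(1 + .data$sd^2 / .data$mean^2)), 0)
    )
  list(
    marginals = marg,
    spearman = spearman_matrix(records, by = "bean_type")
  )
}
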