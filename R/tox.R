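#' Element toxicology table
#'
#' One row per element: the reference dose (`rfd`, mg/kg/day) used for the
#' target hazard quotient, its provenance (`rfd_basis`, `"RfD"` for US-EPA
#' reference doses, `"TDI"` for the FAO/WHO tolerable daily intake used for
#' Pb), the oral slope factor (`sf`, (mg/kg/day)^-1, `NA` for
#' non-carcinogens), the toxic-fraction multiplier `f` converting total
#' measured element to the toxicologically relevant species (0.72 for
#' inorganic As, 1 otherwise), and the assay limits of detection and
#' quantification (`lod`, `loq`, mg/kg; LOD = LOQ / 3.3).
#'
#' @return A tibble with columns `symbol`, `rfd`, `rfd_basis`, `sf`, `f`,
#'   `lod`, `loq`.
#' @examples
#' default_element_tox()
#' @export
default_element_tox <- function() {
  loq <- c(As = 0.0006, Cd = 0.0008, Cr = 0.0006, Hg = 0.0001, Pb = 0.0008)
  tox <- tibble(
    symbol    = .elements,
    rfd       = c(0.0003, 0.0001, 1.5, 0.0001, 0.0036),
    rfd_basis = c("RfD", "RfD", "RfD", "RfD", "TDI"),
    sf        = c(1.5, NA, NA, NA, NA),
    f         = c(0.72, 1, 1, 1, 1),
    lod       = unname(loq / 3.3),
    loq       = unname(loq)
  )
  validate_element_tox(tox)
}

#' Validate an element toxicology table
#'
#' Checks the invariants of the toxicology table: positive reference doses
#' and slope factors where present, toxic fractions in (0, 1], unique
#' element symbols.
#'
#' @param tox A tibble shaped like [default_element_tox()].
#' @return `tox`, invisibly unchanged, or an error.
#' @export
validate_element_tox <- function(tox) {
  stopifnot(is.data.frame(tox))
  needed <- c("symbol", "rfd", "f")
  missing_cols <- setdiff(needed, names(tox))
  if (length(missing_cols) > 0) {
    abort(paste0("toxicology table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tox$symbol)) {
    abort("toxicology table has duplicated element symbols")
  }
  if (any(!is.na(tox$rfd) & tox$rfd <= 0)) {
    abort("reference doses must be > 0 where present")
  }
  if (!is.null(tox$sf) && any(!is.na(tox$sf) & tox$sf <= 0)) {
    abort("slope factors must be > 0 where present")
  }
  if (any(is.na(tox$f) | tox$f <= 0 | tox$f > 1)) {
    abort("toxic fraction f must satisfy 0 < f <= 1 for every element")
  }
  invisible(tox)
}

#' Regulatory maximum limits
#'
#' Maximum limits (ML, mg/kg) for elements in beans: the Chinese national
#' limits of 0.1 mg/kg for Cd, 0.2 mg/kg for Pb and 1.0 mg/kg for Cr,
#' applied uniformly across bean types. As and Hg carry no bean ML and are
#' absent. The tidy (element, bean_type, ml) shape lets per-type limits be
#' supplied where a jurisdiction differentiates them.
#'
#' @return A tibble with columns `element`, `bean_type`, `ml`.
#' @export
default_maximum_limits <- function() {
  tidyr::expand_grid(
    element = c("Cd", "Pb", "Cr"),
    bean_type = .bean_types
  ) |>
    mutate(ml = c(Cd = 0.1, Pb = 0.2, Cr = 1.0)[.data$element])
}

#' Population exposure parameter table
#'
#' One row per population group with the Monte Carlo exposure parameters:
#' ingestion rate `ir` (g/day, fixed), body weight normal parameters
#' `bw_mean`/`bw_sd` (kg), exposure frequency triangular parameters
#' `ef_min`/`ef_mode`/`ef_max` (day/year), exposure duration uniform bounds
#' `ed_min`/`ed_max` (year) and the fixed averaging time `at` (day).
#'
#' Note that the averaging time is fixed per group while exposure duration
#' is a random variable, so EF x ED can exceed AT for some draws; the risk
#' engine flags this in its metadata rather than renormalising.
#'
#' @return A tibble with one row each for `children`, `teens`, `adults`.
#' @examples
#' default_populations()
#' @export
default_populations <- function() {
  pops <- tibble(
    population = c("children", "teens", "adults"),
    ir      = c(32.9, 58.87, 42.75),
    bw_mean = c(16.68, 46.25, 57.03),
    bw_sd   = c(1.48, 1.18, 1.10),
    ef_min  = 180, ef_mode = 345, ef_max = 365,
    ed_min  = c(1, 8, 26),
    ed_max  = c(7, 25, 70),
    at      = c(2190, 5475, 18250)
  )
  validate_populations(pops)
}

#' Validate a population parameter table
#'
#' @param pops A tibble shaped like [default_populations()].
#' @return `pops`, invisibly unchanged, or an error.
#' @export
validate_populations <- function(pops) {
  stopifnot(is.data.frame(pops))
  needed <- c("population", "ir", "bw_mean", "bw_sd",
              "ef_min", "ef_mode", "ef_max", "ed_min", "ed_max", "at")
  missing_cols <- setdiff(needed, names(pops))
  if (length(missing_cols) > 0) {
    abort(paste0("population table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  num <- pops[setdiff(needed, "population")]
  if (any(vapply(num, function(x) any(!is.finite(x) | x <= 0), logical(1)))) {
    abort("all population parameters must be finite and positive")
  }
  if (any(pops$ef_min > pops$ef_mode | pops$ef_mode > pops$ef_max)) {
    abort("exposure frequency requires ef_min <= ef_mode <= ef_max")
  }
  if (any(pops$ed_min >= pops$ed_max)) {
    abort("exposure duration requires ed_min < ed_max")
  }
  invisible(pops)
}

# resolve a population argument: name, one-row data frame, or NULL
resolve_population <- function(population, pops = default_populations()) {
  if (is.character(population)) {
    row <- pops[pops$population == population, ]
    if (nrow(row) != 1) {
      abort(paste0("unknown population '", population, "'; available: ",
                   paste(pops$population, collapse = ", ")))
    }
    return(row)
  }
  if (is.data.frame(population) && nrow(population) == 1) {
    validate_populations(population)
    return(as_tibble(population))
  }
  abort("`population` must be a group name or a one-row parameter table")
}

#' Read and write toxicology / population configuration files
#'
#' Round-trip serialisation of the toxicology and population tables to
#' YAML. Values survive the round trip without drift (numbers are written
#' with full precision).
#'
#' @param path File path.
#' @param tox,pops Tables as returned by [default_element_tox()] /
#'   [default_populations()].
#' @return The read functions return the table; the write functions return
#'   `path` invisibly.
#' @export
write_tox_config <- function(tox, path) {
  yaml::write_yaml(
    list(elements = df_to_rowlist(tox)),
    path, precision = 15
  )
  invisible(path)
}

#' @rdname write_tox_config
#' @export
read_tox_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tox <- rowlist_to_df(raw$elements)
  validate_element_tox(tox)
  tox
}

#' @rdname write_tox_config
#' @export
write_population_config <- function(pops, path) {
  yaml::write_yaml(
    list(populations = df_to_rowlist(pops)),
    path, precision = 15
  )
  invisible(path)
}

#' @rdname write_tox_config
#' @export
read_population_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pops <- rowlist_to_df(raw$populations)
  validate_populations(pops)
  pops
}

df_to_rowlist <- function(df) {
  purrr::pmap(df, function(...) {
    row <- list(...)
    row[!vapply(row, function(x) is.atomic(x) && length(x) == 1 && is.na(x),
                logical(1))]
  })
}

rowlist_to_df <- function(rows) {
  purrr::map(rows, \(r) as_tibble(r)) |>
    purrr::list_rbind()
}
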