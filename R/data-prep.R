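#' Read concentration records from CSV
#'
#' Expected header: `sample_id,area,bean_type,element,value,censored,lod`.
#' An empty `value` with `censored = 1` encodes a non-detect at the stated
#' limit of detection.
#'
#' @param path CSV file path.
#' @return A tibble of concentration records.
#' @export
read_concentration_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "area", "bean_type", "element",
              "value", "censored", "lod")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("concentration CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  df |>
    mutate(
      value = as.numeric(.data$value),
      censored = as.logical(as.integer(.data$censored)),
      lod = as.numeric(.data$lod)
    ) |>
    as_tibble()
}

#' Write concentration records to CSV
#'
#' @param records A concentration-record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_csv <- function(records, path) {
  out <- records |>
    mutate(censored = as.integer(.data$censored))
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Substitute non-detects by the WHO LOD/2 rule
#'
#' Within each (bean type, element) group, censored values are replaced by
#' half their limit of detection. The WHO low-content assessment method
#' endorses this when at most 60% of the group is censored; groups whose
#' censored proportion exceeds the threshold are substituted the same way
#' but flagged `above_who_threshold` in the attached censoring report (a
#' group censored at exactly 60% is within the rule). Detected values are
#' never altered, and the operation is idempotent.
#'
#' @param records A concentration-record tibble (columns as in
#'   [read_concentration_csv()]).
#' @param threshold Censored-proportion threshold for the flag; default 0.6.
#' @return The records with censored values filled in (the `censored` flag
#'   is retained), carrying the per-group censoring report as attribute
#'   `"censoring_report"`; retrieve it with [censoring_report()].
#' @export
substitute_nondetects <- function(records, threshold = 0.6) {
  bad <- records$censored & (is.na(records$lod) | records$lod <= 0)
  if (any(bad)) {
    abort(paste0("censored record(s) without a positive LOD: ",
                 paste(head(records$sample_id[bad], 5), collapse = ", ")))
  }
  report <- records |>
    group_by(.data$bean_type, .data$element) |>
    summarise(
      n = dplyr::n(),
      n_censored = sum(.data$censored),
      prop_censored = mean(.data$censored),
      above_who_threshold = mean(.data$censored) > threshold,
      .groups = "drop"
    )
  out <- records |>
    mutate(value = ifelse(.data$censored, .data$lod / 2, .data$value))
  attr(out, "censoring_report") <- report
  out
}

#' @rdname substitute_nondetects
#' @param x A tibble returned by [substitute_nondetects()].
#' @export
censoring_report <- function(x) {
  rep <- attr(x, "censoring_report")
  if (is.null(rep)) abort("no censoring report attached; run substitute_nondetects() first")
  rep
}

#' Summarise concentrations per bean type and element
#'
#' Produces the descriptive table: n, median, mean, maximum, 95th
#' percentile and SD per (bean type, element), plus the count of samples
#' strictly above the regulatory maximum limit where one exists. Quantiles
#' use linear interpolation between order statistics (R's default type-7
#' convention), the single convention used throughout the package.
#'
#' @param records Substituted concentration records.
#' @param mls Maximum-limit table as from [default_maximum_limits()]; `NULL`
#'   to skip exceedance counting.
#' @return A tibble with one row per (bean_type, element).
#' @export
summarize_concentrations <- function(records, mls = default_maximum_limits()) {
  if (any(is.na(records$value))) {
    warn("records contain missing values; did you run substitute_nondetects()?")
  }
  out <- records |>
    filter(!is.na(.data$value)) |>
    group_by(.data$bean_type, .data$element) |>
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      mean = mean(.data$value),
      max = max(.data$value),
      p95 = quantile(.data$value, 0.95, names = FALSE),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      .groups = "drop"
    )
  if (!is.null(mls)) {
    over <- records |>
      filter(!is.na(.data$value)) |>
      inner_join(mls, by = c("bean_type", "element")) |>
      group_by(.data$bean_type, .data$element) |>
      summarise(n_over_ml = sum(.data$value > .data$ml), .groups = "drop")
    out <- left_join(out, over, by = c("bean_type", "element"))
  } else {
    out$n_over_ml <- NA_integer_
  }
  out
}

#' Correlation strength category
#'
#' Labels the absolute Spearman correlation with the conventional strength
#' bands: weak 0.01-0.39, moderate 0.40-0.59, strong 0.60-0.79, very
#' strong 0.80-1. Band membership is decided on |r| rounded to two
#' decimals, so r = 0.399 is "moderate" and r = 0.394 "weak"; |r| rounding
#' to 0.00 is "negligible".
#'
#' @param r Correlation coefficient(s) in `[-1, 1]` (NA allowed).
#' @return Character vector of category labels.
#' @examples
#' correlation_strength(c(0.934, 0.524, 0.399, 0.005))
#' @export
correlation_strength <- function(r) {
  a <- round(abs(r) + 1e-12, 2)  # round half up at the band edges
  dplyr::case_when(
    is.na(r)  ~ NA_character_,
    a < 0.01  ~ "negligible",
    a < 0.40  ~ "weak",
    a < 0.60  ~ "moderate",
    a < 0.80  ~ "strong",
    TRUE      ~ "very strong"
  )
}

#' Pairwise Spearman correlation of elements
#'
#' Spearman rank correlation (tie-corrected, via [stats::cor.test()]) for
#' every pair of elements across samples, with two-sided p-values and the
#' strength category of [correlation_strength()]. Computed pooled over all
#' samples or within each bean type.
#'
#' @param records Substituted concentration records.
#' @param by `"pooled"` (default) or `"bean_type"`.
#' @return A tidy tibble with columns `bean_type` (when `by =
#'   "bean_type"`), `element1`, `element2`, `n`, `r`, `p`, `category`.
#'   Degenerate (constant) vectors yield `NA` correlations.
#' @export
spearman_matrix <- function(records, by = c("pooled", "bean_type")) {
  by <- match.arg(by)
  groups <- if (by == "pooled") list(`_all_` = records) else
    split(records, records$bean_type)
  out <- purrr::imap(groups, function(g, nm) {
    wide <- g |>
      select("sample_id", "element", "value") |>
      tidyr::pivot_wider(names_from = "element", values_from = "value")
    els <- intersect(.elements, names(wide))
    if (length(els) < 2) return(NULL)
    pairs <- utils::combn(els, 2, simplify = FALSE)
    purrr::map(pairs, function(pr) {
      x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
      ok <- stats::complete.cases(x, y)
      x <- x[ok]; y <- y[ok]
      if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(
          cor.test(x, y, method = "spearman", exact = FALSE)
        )
        r <- unname(ct$estimate); p <- ct$p.value
      }
      tibble(bean_type = nm, element1 = pr[1], element2 = pr[2],
             n = length(x), r = r, p = p,
             category = correlation_strength(r))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  if (by == "pooled") out$bean_type <- NULL
  out
}

#' Widen a tidy correlation table into a matrix
#'
#' @param cor_tbl Output of [spearman_matrix()] (one group).
#' @param value Which column to spread: `"r"` (default) or `"p"`.
#' @return A symmetric matrix with unit (for `r`) diagonal.
#' @export
correlation_matrix <- function(cor_tbl, value = "r") {
  els <- sort(unique(c(cor_tbl$element1, cor_tbl$element2)))
  m <- matrix(NA_real_, length(els), length(els), dimnames = list(els, els))
  diag(m) <- if (value == "r") 1 else 0
  for (i in seq_len(nrow(cor_tbl))) {
    m[cor_tbl$element1[i], cor_tbl$element2[i]] <- cor_tbl[[value]][i]
    m[cor_tbl$element2[i], cor_tbl$element1[i]] <- cor_tbl[[value]][i]
  }
  m
}

#' Kruskal-Wallis screen across groups
#'
#' Per-element Kruskal-Wallis rank-sum test of concentration differences
#' across sampling areas or bean types (tie-corrected H, chi-square
#' p-value). Intended as a screening step; a degenerate element whose
#' values are all identical is reported with H = 0, p = 1.
#'
#' @param records Substituted concentration records.
#' @param group_by `"area"` or `"bean_type"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble with columns `element`, `h`, `df`, `p`, `significant`.
#' @export
kruskal_wallis_screen <- function(records, group_by = c("area", "bean_type"),
                                  alpha = 0.05) {
  group_by <- match.arg(group_by)
  dat <- filter(records, !is.na(.data$value))
  split(dat, dat$element) |>
    purrr::imap(function(g, el) {
      grp <- factor(g[[group_by]])
      if (nlevels(droplevels(grp)) < 2) {
        abort(paste0("element '", el, "' has fewer than 2 groups by ",
                     group_by))
      }
      if (sd(g$value) == 0) {
        h <- 0; df <- nlevels(droplevels(grp)) - 1L; p <- 1
      } else {
        kt <- kruskal.test(g$value, droplevels(grp))
        h <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
      }
      tibble(element = el, h = h, df = df, p = p,
             significant = p < alpha)
    }) |>
    purrr::list_rbind()
}

#' Ward clustering of sampling areas
#'
#' Computes a 5-element mean-concentration profile per area, optionally
#' standardises each element to zero mean / unit SD (element scales differ
#' by orders of magnitude, so this is the default), and clusters the areas
#' by Ward's minimum-variance method (squared Euclidean merge cost;
#' `hclust(method = "ward.D2")` on Euclidean distances). The dendrogram is
#' cut into `k` clusters.
#'
#' @param records Substituted concentration records.
#' @param k Number of clusters to cut (default 3).
#' @param standardize Z-score each element across areas first (default
#'   `TRUE`).
#' @return An `area_clusters` object: list with elements `hclust`,
#'   `clusters` (tibble area/cluster), `profiles` (area x element matrix as
#'   clustered), `k`, `standardized`. Merge heights are non-decreasing.
#' @export
cluster_areas <- function(records, k = 3, standardize = TRUE) {
  prof <- records |>
    filter(!is.na(.data$value)) |>
    group_by(.data$area, .data$element) |>
    summarise(mean = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "element", values_from = "mean")
  m <- as.matrix(prof[-1])
  rownames(m) <- prof$area
  if (nrow(m) < k) {
    abort(paste0("need at least k = ", k, " areas, found ", nrow(m)))
  }
  if (anyNA(m)) {
    abort("every area needs a mean for every element; found missing cells")
  }
  if (standardize) {
    m <- apply(m, 2, function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0)
  }
  hc <- hclust(dist(m), method = "ward.D2")
  labels <- cutree(hc, k = k)
  structure(
    list(
      hclust = hc,
      clusters = tibble(area = names(labels), cluster = unname(labels)),
      profiles = m,
      k = k,
      standardized = standardize
    ),
    class = "area_clusters"
  )
}

#' @export
print.area_clusters <- function(x, ...) {
  cat("Ward clustering of", nrow(x$profiles), "areas into", x$k,
      "clusters", if (x$standardized) "(standardized profiles)", "\n")
  for (cl in sort(unique(x$clusters$cluster))) {
    cat("  C", cl, ": ",
        paste(x$clusters$area[x$clusters$cluster == cl], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.area_clusters <- function(x, ...) x$clusters

#' Export a dendrogram
#'
#' `cluster_newick()` writes the merge tree as a Newick string (branch
#' lengths from merge heights, via \pkg{ape}); `cluster_merge_tree()`
#' returns it as a nested list ready for JSON serialisation.
#'
#' @param x An `area_clusters` object.
#' @return A Newick string / a nested list.
#' @export
cluster_newick <- function(x) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(x$hclust))
}

#' @rdname cluster_newick
#' @export
cluster_merge_tree <- function(x) {
  hc <- x$hclust
  build <- function(i) {
    if (i < 0) {
      list(leaf = hc$labels[-i])
    } else {
      list(height = hc$height[i],
           children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
    }
  }
  build(nrow(hc$merge))
}
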