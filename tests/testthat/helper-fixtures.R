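# shared fixture builders and independent oracles

# build a concentration-record tibble from values; censored entries are NA
make_records <- function(values, element = "Cd", bean_type = "soybean",
                         area = "Hangzhou", lod = 0.0006) {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_along(values)),
    area = area,
    bean_type = bean_type,
    element = element,
    value = values,
    censored = is.na(values),
    lod = lod
  )
}

# records for several elements measured on the same samples
make_multi_element_records <- function(value_matrix, bean_type = "soybean",
                                       area = "Hangzhou") {
  els <- colnames(value_matrix)
  purrr::map(els, function(el) {
    make_records(value_matrix[, el], element = el, bean_type = bean_type,
                 area = area)
  }) |> purrr::list_rbind()
}

# brute-force Ward oracle: best k-partition by total within-cluster
# sum of squares, enumerating every assignment (tiny n only)
brute_force_ward <- function(x, k) {
  n <- nrow(x)
  best <- NULL
  best_ss <- Inf
  assignments <- expand.grid(rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(assignments))) {
    a <- as.integer(assignments[i, ])
    if (length(unique(a)) != k) next
    ss <- sum(vapply(unique(a), function(g) {
      xg <- x[a == g, , drop = FALSE]
      sum(scale(xg, scale = FALSE)^2)
    }, numeric(1)))
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- a
    }
  }
  list(assignment = best, ss = best_ss)
}

# partitions agree up to label permutation
same_partition <- function(a, b) {
  identical(unname(split(seq_along(a), a) |> lapply(unname) |> unname() |>
                     (\(x) x[order(vapply(x, min, 1L))])()),
            unname(split(seq_along(b), b) |> lapply(unname) |> unname() |>
                     (\(x) x[order(vapply(x, min, 1L))])()))
}
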