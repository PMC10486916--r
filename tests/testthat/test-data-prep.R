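# censoring, summaries, correlation, Kruskal-Wallis, clustering

test_that("non-detects become LOD/2 and the WHO flag respects the 60% boundary", {
  v <- c(rep(NA, 3), runif(7, 0.001, 0.01))
  recs <- make_records(v, lod = 0.0006)
  out <- substitute_nondetects(recs)
  expect_equal(out$value[1:3], rep(0.0003, 3))
  expect_equal(out$value[4:10], recs$value[4:10])
  rep1 <- censoring_report(out)
  expect_equal(rep1$prop_censored, 0.3)
  expect_false(rep1$above_who_threshold)

  # exactly 60% censored still substitutes without the flag
  recs60 <- make_records(c(rep(NA, 6), runif(4, 0.001, 0.01)))
  rep60 <- censoring_report(substitute_nondetects(recs60))
  expect_equal(rep60$prop_censored, 0.6)
  expect_false(rep60$above_who_threshold)

  # 7/10 censored: substituted all the same, but flagged
  recs70 <- make_records(c(rep(NA, 7), runif(3, 0.001, 0.01)))
  out70 <- substitute_nondetects(recs70)
  expect_true(censoring_report(out70)$above_who_threshold)
  expect_equal(out70$value[1:7], rep(0.0003, 7))

  # no censoring: unchanged, proportion zero
  recs0 <- make_records(runif(5, 0.001, 0.01))
  out0 <- substitute_nondetects(recs0)
  expect_equal(out0$value, recs0$value)
  expect_equal(censoring_report(out0)$prop_censored, 0)

  # censored record without an LOD is a data error naming the record
  bad <- make_records(c(NA, 0.002))
  bad$lod[1] <- NA
  expect_error(substitute_nondetects(bad), "S001")
})

test_that("substitution is idempotent and never alters detected values", {
  set.seed(33)
  for (i in 1:10) {
    v <- runif(30, 0.0001, 0.02)
    v[runif(30) < runif(1, 0, 0.8)] <- NA
    recs <- make_records(v, lod = 0.0008)
    once <- substitute_nondetects(recs)
    twice <- substitute_nondetects(once)
    expect_equal(twice$value, once$value)
    detected <- !recs$censored
    expect_equal(once$value[detected], recs$value[detected])
  }
})

test_that("summaries match direct computation and count ML exceedances strictly", {
  v <- c(0.05, 0.489, 0.02, 0.12)
  recs <- make_records(v, element = "Cd", bean_type = "soybean")
  sm <- summarize_concentrations(substitute_nondetects(recs))
  expect_equal(sm$n, 4)
  expect_equal(sm$median, median(v))
  expect_equal(sm$mean, mean(v))
  expect_equal(sm$max, 0.489)
  expect_equal(sm$n_over_ml, 2)  # ML(Cd) = 0.1, strict >

  # boundary-equal value does not count as exceedance
  sm_eq <- summarize_concentrations(
    substitute_nondetects(make_records(c(0.1, 0.05), element = "Cd")))
  expect_equal(sm_eq$n_over_ml, 0)

  # constant group: all statistics collapse, sd 0
  smc <- summarize_concentrations(
    substitute_nondetects(make_records(rep(0.02, 6), element = "Hg")))
  expect_equal(smc$median, 0.02)
  expect_equal(smc$p95, 0.02)
  expect_equal(smc$sd, 0)
  expect_true(is.na(smc$n_over_ml) || is.null(smc$n_over_ml))

  # p95 follows the type-7 interpolation convention (hand formula, n = 12)
  set.seed(4)
  v12 <- sort(runif(12, 0, 1))
  h <- 0.95 * 11 + 1
  expected_p95 <- v12[floor(h)] + (h - floor(h)) * (v12[ceiling(h)] - v12[floor(h)])
  sm12 <- summarize_concentrations(substitute_nondetects(make_records(v12)))
  expect_equal(sm12$p95, expected_p95, tolerance = 1e-12)
  expect_true(sm12$median <= sm12$p95 && sm12$p95 <= sm12$max)
})

test_that("summaries are invariant to record order", {
  set.seed(5)
  recs <- make_records(runif(25, 0.001, 0.3))
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(summarize_concentrations(substitute_nondetects(recs)),
               summarize_concentrations(substitute_nondetects(shuffled)))
})

test_that("correlation strength categories follow the printed bands", {
  expect_equal(correlation_strength(0.934), "very strong")
  expect_equal(correlation_strength(0.524), "moderate")
  expect_equal(correlation_strength(0.399), "moderate")  # rounds to 0.40
  expect_equal(correlation_strength(0.394), "weak")
  expect_equal(correlation_strength(0.72), "strong")
  expect_equal(correlation_strength(-0.85), "very strong")
  expect_equal(correlation_strength(0.004), "negligible")
  expect_equal(correlation_strength(c(0.395, 0.595, 0.795)),
               c("moderate", "strong", "very strong"))
})

test_that("spearman_matrix agrees with cor.test and handles degenerate inputs", {
  set.seed(8)
  n <- 40
  x <- rlnorm(n); y <- 0.7 * x + rlnorm(n, sdlog = 0.5); z <- rlnorm(n)
  recs <- make_multi_element_records(cbind(Cd = x, Pb = y, Hg = z))
  tbl <- spearman_matrix(recs)
  cdpb <- tbl[tbl$element1 == "Cd" & tbl$element2 == "Pb", ]
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(cdpb$r, unname(ct$estimate))
  expect_equal(cdpb$p, ct$p.value)
  expect_equal(cdpb$category, correlation_strength(cdpb$r))

  # perfectly monotone pair: r = 1
  recs2 <- make_multi_element_records(cbind(Cd = 1:10, Pb = (1:10)^2))
  tbl2 <- spearman_matrix(recs2)
  expect_equal(tbl2$r, 1)

  # constant vector: correlation undefined, reported as NA
  recs3 <- make_multi_element_records(cbind(Cd = rep(0.2, 8), Pb = runif(8)))
  expect_true(is.na(spearman_matrix(recs3)$r))

  # the widened matrix is symmetric with a unit diagonal
  m <- correlation_matrix(tbl)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, ncol(m)))
})

test_that("kruskal-wallis screen matches hand rank arithmetic", {
  recs <- dplyr::bind_rows(
    make_records(c(1, 2, 3), area = "Hangzhou"),
    make_records(c(10, 11, 12), area = "Ningbo")
  )
  kw <- kruskal_wallis_screen(recs, group_by = "area")
  # ranks 1..6; H = 12/(6*7) * (6^2/3 + 15^2/3) - 3*7 = 27/7
  expect_equal(kw$h, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$p, stats::pchisq(27 / 7, df = 1, lower.tail = FALSE))

  # identical distributions across groups: H = 0
  same <- dplyr::bind_rows(
    make_records(c(1, 2, 3), area = "Hangzhou"),
    make_records(c(1, 2, 3), area = "Ningbo")
  )
  expect_equal(kruskal_wallis_screen(same, "area")$h, 0, tolerance = 1e-12)

  # all values tied everywhere: guarded H = 0, p = 1
  tied <- dplyr::bind_rows(
    make_records(rep(2, 3), area = "Hangzhou"),
    make_records(rep(2, 3), area = "Ningbo"),
    make_records(rep(2, 3), area = "Wenzhou")
  )
  kt <- kruskal_wallis_screen(tied, "area")
  expect_equal(kt$h, 0)
  expect_equal(kt$p, 1)

  expect_error(kruskal_wallis_screen(make_records(1:5), "area"),
               "fewer than 2 groups")
})

test_that("ward clustering recovers planted structure and the brute-force optimum", {
  # three well-separated planted area groups
  set.seed(13)
  centers <- list(c(0, 0, 0, 0, 0), c(5, 5, 5, 5, 5), c(-5, 5, -5, 5, -5))
  truth <- rep(1:3, each = 3)
  recs <- purrr::imap(
    setNames(centers[truth], paste0("area", seq_along(truth))),
    function(ctr, ar) {
      vals <- matrix(rep(ctr, each = 4), ncol = 5) + rnorm(20, sd = 0.1)
      colnames(vals) <- c("As", "Cd", "Cr", "Hg", "Pb")
      make_multi_element_records(vals, area = ar)
    }) |> purrr::list_rbind()
  cl <- cluster_areas(recs, k = 3)
  got <- cl$clusters$cluster[match(paste0("area", seq_along(truth)),
                                   cl$clusters$area)]
  expect_true(same_partition(got, truth))
  # Ward merge heights are monotone non-decreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-10))

  # brute-force Ward objective on single-element profiles [0], [1], [10]
  prof <- matrix(c(0, 1, 10), ncol = 1)
  oracle <- brute_force_ward(prof, k = 2)
  recs1 <- purrr::imap(
    setNames(c(0, 1, 10) + 1, c("a1", "a2", "a3")),  # shift: values > 0
    \(v, ar) make_records(rep(v, 3), area = ar)
  ) |> purrr::list_rbind()
  cl1 <- cluster_areas(recs1, k = 2, standardize = FALSE)
  got1 <- cl1$clusters$cluster[match(c("a1", "a2", "a3"), cl1$clusters$area)]
  expect_true(same_partition(got1, oracle$assignment))  # {0,1} vs {10}
  expect_true(same_partition(oracle$assignment, c(1, 1, 2)))

  # identical profiles merge first at height zero
  recs_eq <- dplyr::bind_rows(
    make_records(rep(0.5, 3), area = "x1"),
    make_records(rep(0.5, 3), area = "x2"),
    make_records(rep(0.9, 3), area = "x3")
  )
  cl_eq <- cluster_areas(recs_eq, k = 2, standardize = FALSE)
  expect_equal(cl_eq$hclust$height[1], 0, tolerance = 1e-12)

  expect_error(cluster_areas(recs_eq, k = 5), "at least k")
})

test_that("dendrogram exports are consistent with the merge history", {
  recs <- purrr::imap(
    setNames(c(1, 2, 8, 9), paste0("a", 1:4)),
    \(v, ar) make_records(rep(v, 2), area = ar)
  ) |> purrr::list_rbind()
  cl <- cluster_areas(recs, k = 2, standardize = FALSE)
  tree <- cluster_merge_tree(cl)
  expect_equal(tree$height, max(cl$hclust$height))
  nwk <- cluster_newick(cl)
  expect_match(nwk, "^\\(")
  expect_true(all(vapply(paste0("a", 1:4), grepl, logical(1), nwk)))
})
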