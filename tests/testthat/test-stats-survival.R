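test_that("Mann-Whitney matches full enumeration on small tie-free inputs", {
  # systematic sweep of sample sizes
  set.seed(50)
  for (n in 1:5) for (m in 1:(10 - n)) {
    v <- sample(stats::runif(n + m))
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    got <- mann_whitney_u(x, y)
    oracle <- mw_enum(x, y)
    expect_equal(got$u, oracle$u)
    expect_equal(got$p_value, oracle$p, tolerance = 1e-12)
  }
  # named examples
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$u, 0)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p_value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(mann_whitney_u(1:4, 1:4)$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "at least one")
})

test_that("U statistics of the two orientations sum to n*m", {
  set.seed(51)
  for (i in 1:20) {
    x <- stats::rnorm(sample(2:8, 1))
    y <- stats::rnorm(sample(2:8, 1))
    expect_equal(mann_whitney_u(x, y)$u + mann_whitney_u(y, x)$u,
                 length(x) * length(y))
  }
})

test_that("Spearman correlation equals Pearson on ranks", {
  set.seed(52)
  x <- stats::rnorm(10); y <- stats::rnorm(10)
  expect_equal(spearman_cor(x, y)$rho,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:3, 1:4), "equal length")
})

test_that("Fisher's exact test equals the hypergeometric tail sum", {
  tabs <- list(
    matrix(c(5, 5, 5, 5), 2),
    matrix(c(10, 0, 0, 10), 2),
    matrix(c(3, 7, 8, 2), 2),
    matrix(c(1, 9, 4, 6), 2),
    matrix(c(0, 4, 9, 1), 2)
  )
  for (tab in tabs) {
    expect_equal(fisher_exact(tab)$p_value, fisher_enum(tab),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value, 2 / 184756,
               tolerance = 1e-9)
  # invariant under row and column swaps
  tab <- matrix(c(3, 7, 8, 2), 2)
  expect_equal(fisher_exact(tab)$p_value, fisher_exact(tab[2:1, ])$p_value)
  expect_equal(fisher_exact(tab)$p_value, fisher_exact(tab[, 2:1])$p_value)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("log-rank statistic matches the hand-computed 2x2 event tables", {
  # events at t = 1, 2 in arm A (2 patients); arm B censored at t = 3
  d <- tibble::tibble(time_months = c(1, 2, 3), event = c(1, 1, 0))
  grp <- c("A", "A", "B")
  km <- km_logrank(d, grp)
  # t=1: A has 2/3 at risk, 1 event -> E_A = 2/3, V = (2/3)(1/3)
  # t=2: A has 1/2 at risk, 1 event -> E_A = 1/2, V = (1/2)(1/2)
  o_minus_e <- (1 - 2 / 3) + (1 - 1 / 2)
  v <- (2 / 3) * (1 / 3) + (1 / 2) * (1 / 2)
  expect_equal(km$chisq, o_minus_e^2 / v, tolerance = 1e-9)
  expect_equal(km$groups$label, c("2 (2)", "1 (0)"))
  # identical patterns in both groups -> chi-square 0, p = 1
  d2 <- tibble::tibble(time_months = rep(c(2, 5, 9), 2),
                       event = rep(c(1, 1, 0), 2))
  km2 <- km_logrank(d2, rep(c("A", "B"), each = 3))
  expect_equal(km2$chisq, 0, tolerance = 1e-9)
  expect_equal(km2$p_value, 1)
  # invariant under consistent group relabeling
  km3 <- km_logrank(d, c("B", "B", "A"))
  expect_equal(km3$chisq, km$chisq)
})

test_that("KM curve equals the empirical survival function without censoring", {
  times <- c(2, 4, 4, 7, 10)
  d <- tibble::tibble(time_months = c(times, 1, 3),
                      event = c(rep(1, 5), 1, 1))
  km <- km_logrank(d, c(rep("A", 5), "B", "B"))
  td <- tidy(km)
  a <- td[td$group == "A", ]
  ecdf_surv <- 1 - stats::ecdf(times)(a$time)
  expect_equal(a$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("input contracts for survival comparison hold", {
  d <- tibble::tibble(time_months = c(1, 2), event = c(1, 0))
  expect_error(km_logrank(d, c("A", "A")), "2 groups")
  expect_error(
    km_logrank(tibble::tibble(time_months = c(-1, 2), event = c(1, 0)),
               c("A", "B")), "positive")
  expect_error(
    km_logrank(tibble::tibble(time_months = c(1, 2), event = c(0, 0)),
               c("A", "B")), "one event")
})

test_that("dichotomization rules split patients as specified", {
  expect_equal(as.character(dichotomize(1:8, "median")),
               rep(c("low", "high"), each = 4))
  # lowest quartile of 8 values -> 2 in the low group
  expect_equal(sum(dichotomize(1:8, "lowest_quartile") == "low"), 2)
  si <- c(0, 0, 3, 6, 9, 1)
  z <- dichotomize(si, "zero_vs_positive")
  expect_equal(which(z == "loss"), which(si == 0))
  expect_error(dichotomize(rep(2, 6), "median"), "degenerate")
  expect_error(dichotomize(1:3, "lowest_quartile"), "at least 4")
})

test_that("staining index is the product with codomain {0,1,2,3,4,6,9}", {
  grid <- expand.grid(i = 0:3, a = 1:3)
  si <- staining_index(grid$i, grid$a)
  expect_setequal(si, c(0, 1, 2, 3, 4, 6, 9))
  expect_equal(max(si), 9)
  expect_true(all(staining_index(0, 1:3) == 0))
  expect_equal(staining_index(3, 3), 9)
  expect_equal(staining_index(2, 3), 6)
  expect_error(staining_index(4, 1), "intensity_score")
  expect_error(staining_index(1, 0), "area_score")
})

test_that("purity selection takes the floor(fraction * n) lowest scores", {
  set.seed(53)
  scores <- tibble::tibble(sample_id = sprintf("s%03d", 1:254),
                           score = stats::rnorm(254))
  sel <- select_high_purity(scores, fraction = 0.33)
  expect_equal(nrow(sel), 83)
  # brute-force sort-and-slice oracle
  oracle <- scores$sample_id[order(scores$score, scores$sample_id)][1:83]
  expect_setequal(sel$sample_id, oracle)
  expect_equal(nrow(select_high_purity(stats::rnorm(10), 0.33)), 3)
  expect_error(select_high_purity(stats::rnorm(10), 0.05), "zero samples")
  # deterministic tie-break by id
  tied <- tibble::tibble(sample_id = c("b", "a", "c", "d"),
                         score = c(1, 1, 2, 3))
  expect_equal(select_high_purity(tied, 0.3)$sample_id, "a")
})

test_that("survival recovery holds across seeds at the cohort design", {
  runs <- recovery_runs(50)
  expect_gte(mean(runs$logrank_p < 0.05), 0.9)
})
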