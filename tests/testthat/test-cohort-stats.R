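test_that("rank transformation averages ties and sums to n(n+1)/2", {
  expect_equal(rank_transform(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_transform(c(5, 5, 9)), c(1.5, 1.5, 3))
  expect_error(rank_transform(numeric(0)), "at least 2")

  set.seed(41)
  for (i in 1:20) {
    x <- sample(round(rnorm(12), 1), 12, replace = TRUE)
    r <- rank_transform(x)
    expect_equal(sum(r), 12 * 13 / 2)
    # sort-based oracle with tie-group averaging
    o <- order(x)
    raw <- seq_along(x)[order(o)]
    oracle <- stats::ave(raw, x, FUN = mean)
    expect_equal(r, oracle)
  }
})

test_that("Spearman rho matches the rank formula and cor.test", {
  up <- spearman_cor(1:8, (1:8)^3)
  expect_equal(up$rho, 1)

  # n = 4 with one discordant pair, against the direct rank formula
  x <- c(1, 2, 3, 4); y <- c(1, 2, 4, 3)
  s <- spearman_cor(x, y)
  d <- rank(x) - rank(y)
  expect_equal(s$rho, 1 - 6 * sum(d^2) / (4 * (4^2 - 1)))

  set.seed(42)
  for (n in c(6, 9, 15, 40)) {
    a <- rnorm(n); b <- a + rnorm(n, sd = 2)
    s <- spearman_cor(a, b)
    ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
    expect_equal(s$rho, unname(ct$estimate))
    if (n <= 9) expect_equal(s$p_value, ct$p.value)  # both exact
  }

  const <- spearman_cor(rep(1, 5), 1:5)
  expect_true(is.na(const$rho))
  expect_equal(const$method, "undefined")
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("Spearman is invariant under monotone transforms and symmetry", {
  set.seed(43)
  x <- rnorm(20); y <- x + rnorm(20)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, base)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
})

make_cohort_df <- function(values, genotypes, ages) {
  data.frame(animal_id = sprintf("m%02d", seq_along(values)),
             genotype = genotypes, age_months = ages, value = values,
             stringsAsFactors = FALSE)
}

test_that("ranked two-way ANOVA matches hand-computed balanced sums of squares", {
  # balanced 2x2, n = 3 per cell, values chosen to be their own ranks
  df <- make_cohort_df(
    values = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
    genotypes = rep(c("WT", "TNF-Tg"), each = 6),
    ages = rep(c(3, 12, 3, 12), each = 3))
  res <- two_way_anova_ranked(df)

  r <- rank(df$value)                       # 1..12
  cell_means <- tapply(r, list(df$genotype, df$age_months), mean)
  g_means <- tapply(r, df$genotype, mean)
  a_means <- tapply(r, df$age_months, mean)
  grand <- mean(r)
  ss_g <- 6 * sum((g_means - grand)^2)
  ss_a <- 6 * sum((a_means - grand)^2)
  ss_cells <- 3 * sum((cell_means - grand)^2)
  ss_int <- ss_cells - ss_g - ss_a
  ss_err <- sum((r - cell_means[cbind(df$genotype,
                                      as.character(df$age_months))])^2)
  ms_err <- ss_err / 8
  tab <- res$anova_table
  expect_equal(tab$F[tab$term == "genotype"], (ss_g / 1) / ms_err)
  expect_equal(tab$F[tab$term == "age"], (ss_a / 1) / ms_err)
  expect_equal(tab$F[tab$term == "genotype:age"], (ss_int / 1) / ms_err)

  # all equal values: zero F everywhere
  flat <- make_cohort_df(rep(5, 12), rep(c("WT", "TNF-Tg"), each = 6),
                         rep(c(3, 12, 3, 12), each = 3))
  res0 <- two_way_anova_ranked(flat)
  expect_true(all(res0$anova_table$F == 0))

  # empty cell errors with the cell named
  mis <- df[!(df$genotype == "WT" & df$age_months == 12), ]
  expect_error(two_way_anova_ranked(mis), "empty design cell")
})

test_that("ranked ANOVA detects a genotype shift with high power", {
  hits <- 0
  for (r in 1:200) {
    ch <- generate_cohort(rho_true = 0.5, genotype_effect = 2,
                          n_per_cell = 6, rng_seed = 44000 + r)
    tab <- ch$table[ch$table$outcome == "ct_tissue_volume", ]
    res <- two_way_anova_ranked(tab)
    p <- res$anova_table$p[res$anova_table$term == "genotype"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / 200, 0.9)
})

test_that("Bonferroni timepoint tests use the alpha/k threshold", {
  ch <- generate_cohort(rho_true = 0.5, genotype_effect = 3,
                        n_per_cell = 5, rng_seed = 45)
  tab <- ch$table[ch$table$outcome == "ct_tissue_volume", ]
  bt <- bonferroni_timepoint_tests(tab)
  expect_equal(attr(bt, "threshold"), 0.0125)
  expect_equal(nrow(bt), 4)
  expect_true(all(bt$computable))

  # identical groups are never significant
  flat <- tab; flat$value <- rep(c(1, 2, 3, 4, 5), 8)
  bt0 <- bonferroni_timepoint_tests(flat)
  expect_true(all(!bt0$significant))

  # a timepoint with < 2 per group is flagged, not dropped
  wt3 <- which(tab$age_months == 3 & tab$genotype == "WT")
  thin <- tab[-wt3[-1], ]          # keep a single WT animal at 3 months
  btn <- bonferroni_timepoint_tests(thin)
  expect_false(btn$computable[btn$age_months == 3])
  expect_true(all(btn$computable[btn$age_months != 3]))
})

test_that("Shapiro-Wilk gate flags skewed samples and passes normal ones", {
  expect_error(shapiro_wilk_gate(c(1, 2)), "3 <= n")
  set.seed(46)
  skewed <- mean(replicate(500, {
    shapiro_wilk_gate(rexp(20))$rank_transform_recommended
  }))
  expect_gte(skewed, 0.8)
  normal <- mean(replicate(500, {
    shapiro_wilk_gate(rnorm(20))$normal
  }))
  expect_gte(normal, 0.9)
  expect_lte(normal, 0.99)
})
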