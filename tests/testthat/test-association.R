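# Ordered-haplotype trend model, FDR screening, biadjacency construction.

make_samples <- function(n_per_group) {
  g <- rep(c("FC/FC", "WT/WT", "VS/VS"), n_per_group)
  data.frame(sample_id = sprintf("s%02d", seq_along(g)), genotype = g,
             sex = "F", age_cohort = "12mo", batch = "B1",
             stringsAsFactors = FALSE)
}

test_that("a response equal to the contrast code fits perfectly", {
  s <- make_samples(c(3, 3, 3))
  x <- c(FC = -1, WT = 0, VS = 1)[as.character(haplotype_group(s$genotype))]
  fit <- fit_haplotype_trend(setNames(x, s$sample_id), s, set_id = "perfect")
  expect_equal(fit$beta, 1, tolerance = 1e-12)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-12)
  expect_equal(fit$n_FC, 3)
})

test_that("a 9-sample fit matches the closed-form OLS oracle", {
  s <- make_samples(c(3, 3, 3))
  y <- c(2.1, 1.9, 2.3, 2.6, 2.4, 2.2, 3.0, 2.8, 3.3)
  x <- c(-1, -1, -1, 0, 0, 0, 1, 1, 1)
  o <- trend_oracle(y, x)
  fit <- fit_haplotype_trend(setNames(y, s$sample_id), s)
  expect_equal(fit$beta, o$beta, tolerance = 1e-10)
  expect_equal(fit$p, o$p, tolerance = 1e-10)
  expect_equal(fit$r2_adj, o$r2_adj, tolerance = 1e-10)
  # positive beta <=> fitted VS mean above fitted FC mean
  expect_gt(mean(y[7:9]) - mean(y[1:3]), 0)
  expect_gt(fit$beta, 0)
})

test_that("with equal group sizes beta is half the VS-FC fitted mean difference", {
  set.seed(12)
  for (r in 1:20) {
    s <- make_samples(c(6, 6, 6))
    y <- rnorm(18)
    fit <- fit_haplotype_trend(setNames(y, s$sample_id), s)
    hap <- as.character(haplotype_group(s$genotype))
    expect_equal(fit$beta,
                 (mean(y[hap == "VS"]) - mean(y[hap == "FC"])) / 2,
                 tolerance = 1e-10)
  }
})

test_that("adjusted R2 can be negative and zero variance is degraded gracefully", {
  set.seed(3)
  s <- make_samples(c(4, 4, 4))
  y <- rnorm(12)  # pure noise: adjusted R2 frequently negative
  fits <- replicate(20, fit_haplotype_trend(setNames(rnorm(12), s$sample_id), s)$r2_adj)
  expect_true(any(fits < 0))
  expect_message(
    fitc <- fit_haplotype_trend(setNames(rep(1, 12), s$sample_id), s),
    "zero response variance")
  expect_equal(fitc$beta, 0)
  expect_equal(fitc$p, 1)
})

test_that("missing or tiny haplotype groups are errors", {
  s <- make_samples(c(3, 3, 3))
  s_nofc <- s[haplotype_group(s$genotype) != "FC", ]
  expect_error(fit_haplotype_trend(setNames(rnorm(6), s_nofc$sample_id), s_nofc),
               "absent")
})

test_that("screening retains planted effects at FDR 0.001 with correct signs", {
  set.seed(91)
  s <- make_samples(c(20, 20, 20))
  x <- c(FC = -1, WT = 0, VS = 1)[as.character(haplotype_group(s$genotype))]
  n_sets <- 200; n_true <- 20
  delta <- rep(0, n_sets); delta[1:n_true] <- rep(c(2, -2), 10)
  Y <- t(sapply(seq_len(n_sets), function(i) delta[i] / 2 * x + rnorm(60)))
  rownames(Y) <- sprintf("set%03d", seq_len(n_sets))
  colnames(Y) <- s$sample_id
  fits <- fit_trend_sets(Y, s)
  scr <- screen_sets(fits, fdr = 0.001)
  planted <- sprintf("set%03d", 1:n_true)
  recovered <- intersect(scr$set_id, planted)
  expect_gte(length(recovered), 18)
  sign_ok <- sign(scr$beta[match(recovered, scr$set_id)]) ==
    sign(delta[match(recovered, rownames(Y))])
  expect_true(all(sign_ok))
  expect_lte(sum(!scr$set_id %in% planted), 3)
  # sorted by beta descending
  expect_true(all(diff(scr$beta) <= 0))
})

test_that("screening returns nothing when all p = 1", {
  fits <- data.frame(set_id = paste0("s", 1:5), beta = rnorm(5),
                     r2_adj = 0, p = 1)
  expect_equal(nrow(screen_sets(fits, 0.05)), 0L)
})

test_that("biadjacency places betas, orders by mean |beta|, and rejects duplicates", {
  res <- data.frame(set_id = c("P1 :: D1", "P1 :: D2", "P2 :: D1"),
                    beta = c(0.5, 0.4, -0.1))
  m <- biadjacency(res)
  expect_equal(dim(m), c(2, 2))
  expect_equal(rownames(m)[1], "P1")   # mean |beta| 0.45 > 0.1
  expect_equal(m["P1", "D1"], 0.5)
  expect_true(is.na(m["P2", "D2"]))
  single <- biadjacency(data.frame(set_id = "P :: D", beta = 0.3))
  expect_equal(dim(single), c(1, 1))
  expect_equal(unname(single[1, 1]), 0.3)
  expect_equal(dim(biadjacency(data.frame())), c(0, 0))
  expect_error(
    biadjacency(data.frame(set_id = c("P :: D", "P :: D"), beta = c(1, 2))),
    "duplicate")
})

test_that("a pathway planted across several domains shows a consistent row", {
  set.seed(14)
  s <- make_samples(c(15, 15, 15))
  x <- c(FC = -1, WT = 0, VS = 1)[as.character(haplotype_group(s$genotype))]
  ids <- c(paste0("P1 :: D", 1:4), paste0("P", 2:6, " :: D9"))
  delta <- c(rep(1.5, 4), rep(0, 5))
  Y <- t(sapply(delta, function(d) d / 2 * x + rnorm(45)))
  rownames(Y) <- ids; colnames(Y) <- s$sample_id
  scr <- screen_sets(fit_trend_sets(Y, s), fdr = 0.001)
  m <- biadjacency(scr)
  expect_true(all(m["P1", !is.na(m["P1", ])] > 0))
})
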