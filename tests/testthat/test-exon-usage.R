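# Feature filters, DM likelihood, DM regression fits and the usage LRT.

test_that("feature filters apply both rules inclusively and drop thin genes", {
  n <- 30
  mk <- function(nonzero, level) c(rep(level, nonzero), rep(0, n - nonzero))
  tab <- data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    feature_id = paste0("f", 1:5),
    stringsAsFactors = FALSE)
  counts <- rbind(
    mk(30, 50),          # kept
    mk(9, 50),           # removed: expressed in only 9 samples
    mk(10, 30),          # kept: 10 samples, mean 10.0 exactly
    mk(30, 9),           # removed: mean 9 < 10
    rep(0, n))           # removed: all zero
  colnames(counts) <- paste0("s", 1:n)
  tab <- cbind(tab, counts)
  class(tab) <- c("exon_count_table", "data.frame")
  out <- filter_features(tab, min_samples = 10, min_mean = 10)
  expect_setequal(out$feature_id, c("f1", "f3"))  # gB loses both features
  expect_true(all(out$gene_id == "gA"))

  # randomized tables match brute force
  set.seed(40)
  for (r in 1:5) {
    rt <- data.frame(gene_id = rep(paste0("g", 1:8), each = 3),
                     feature_id = paste0("x", 1:24))
    m <- matrix(rpois(24 * 25, 8), 24, 25,
                dimnames = list(NULL, paste0("s", 1:25)))
    rt <- cbind(rt, m)
    class(rt) <- c("exon_count_table", "data.frame")
    keep <- rowSums(m > 0) >= 10 & rowMeans(m) >= 10
    genes_ok <- names(which(table(rt$gene_id[keep]) >= 2))
    manual <- rt$feature_id[keep & rt$gene_id %in% genes_ok]
    expect_setequal(filter_features(rt)$feature_id, manual)
  }
})

test_that("dm_loglik matches the direct gamma-function pmf and its limits", {
  # counts (3,1), equal proportions, gamma = 2, against direct evaluation
  expect_equal(dm_loglik(c(3, 1), c(0.5, 0.5), 2),
               log(dm_pmf_oracle(c(3, 1), c(0.5, 0.5), 2)),
               tolerance = 1e-12)
  # multinomial limit: counts (2,1) equal proportions -> log(0.375)
  expect_equal(dm_loglik(c(2, 1), c(0.5, 0.5), Inf), log(0.375),
               tolerance = 1e-12)
  expect_equal(dm_loglik(c(2, 1), c(0.5, 0.5), 1e9), log(0.375),
               tolerance = 1e-4)
  # degenerate one-feature simplex
  expect_equal(dm_loglik(5, 1, 3), 0)
  # zero proportion with positive count
  expect_equal(dm_loglik(c(2, 1), c(1, 0), 5), -Inf)
  expect_error(dm_loglik(c(1, 1), c(0.7, 0.7), 1), "simplex")
})

test_that("dm_loglik sums to one over the outcome space", {
  set.seed(50)
  for (K in 2:3) {
    for (n in c(4, 6)) {
      p <- rgamma(K, 2); p <- p / sum(p)
      for (g in c(0.7, 5, 200)) {
        xs <- enumerate_counts(n, K)
        tot <- sum(apply(xs, 1, function(x) exp(dm_loglik(x, p, g))))
        expect_equal(tot, 1, tolerance = 1e-10)
      }
    }
  }
})

test_that("fit_dm recovers proportions and is invariant to sample order", {
  s <- tiny_cohort(5)
  set.seed(60)
  errs <- replicate(40, {
    p <- c(0.5, 0.3, 0.2)
    tot <- rpois(40, 500)
    counts <- sapply(seq_len(40), function(i) {
      w <- rgamma(3, 50 * p)
      rmultinom(1, tot[i], w / sum(w))
    })
    f <- fit_dm(counts, matrix(1, 40, 1))
    max(abs(rowMeans(f$fitted_proportions) - p))
  })
  expect_lt(median(errs), 0.03)

  counts <- matrix(rpois(3 * 12, 40), 3, 12)
  Z <- cbind(1, rep(c(0, 1), each = 6))
  f1 <- fit_dm(counts, Z)
  perm <- sample(12)
  f2 <- fit_dm(counts[, perm], Z[perm, , drop = FALSE])
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("a single-sample intercept fit returns the observed proportions", {
  counts <- matrix(c(30, 50, 20), 3, 1)
  f <- fit_dm(counts, matrix(1, 1, 1))
  expect_equal(as.numeric(f$fitted_proportions), c(0.3, 0.5, 0.2),
               tolerance = 1e-3)
})

test_that("the LR statistic does not depend on the reference feature", {
  set.seed(70)
  s <- tiny_cohort(3)
  ex <- simulate_exon_counts(s, list(dtu_truth("dgene0001", 1, 0.15)),
                             n_genes = 2, features_per_gene = 3,
                             depth = 300, seed = 71)
  keep <- s$haplotype_group %in% c("FC", "VS")
  ss <- s[keep, ]
  dat <- data.frame(batch = factor(ss$batch), sex = factor(ss$sex),
                    grp = factor(as.character(ss$haplotype_group)))
  Xf <- model.matrix(~ ., dat)
  Xr <- model.matrix(~ batch + sex, dat)
  b <- exon_blocks(ex)[["dgene0001"]][, ss$sample_id]
  lr <- function(block) {
    2 * (fit_dm(block, Xf)$loglik - fit_dm(block, Xr)$loglik)
  }
  lr1 <- lr(b)
  lr2 <- lr(b[c(3, 1, 2), ])    # rotate which feature is last (reference)
  expect_equal(lr1, lr2, tolerance = 1e-3)
})

test_that("dtu_test excludes WT, reports the stated df, and finds planted shifts", {
  s <- tiny_cohort(4)
  tr <- lapply(1:3, function(i) dtu_truth(sprintf("dgene%04d", i), 1, 0.3,
                                          precision = 50))
  ex <- simulate_exon_counts(s, tr, n_genes = 10, features_per_gene = 3,
                             depth = 500, precision = 50, seed = 80)
  res <- dtu_test(filter_features(ex), s)
  expect_true(all(res$df[res$converged] == res$n_features[res$converged] - 1))
  planted <- res$gene_id %in% sprintf("dgene%04d", 1:3)
  expect_true(all(res$p_adj[planted] <= 0.05, na.rm = TRUE))
  expect_error(dtu_test(filter_features(ex), s[s$haplotype_group == "FC", ]),
               ">= 3 samples")
})

test_that("at very large precision the LRT agrees with a direct multinomial LRT", {
  set.seed(90)
  s <- tiny_cohort(3)
  ex <- simulate_exon_counts(s, n_genes = 5, features_per_gene = 3,
                             depth = 200, precision = Inf, seed = 91)
  keep <- s$haplotype_group %in% c("FC", "VS")
  ss <- s[keep, ]
  blocks <- exon_blocks(ex)
  # direct multinomial LRT oracle: saturated-by-group vs pooled proportions,
  # restricted to the intercept + group design (no covariates)
  Xf <- model.matrix(~ grp, data.frame(grp = factor(as.character(ss$haplotype_group))))
  Xr <- matrix(1, nrow(ss), 1)
  for (g in names(blocks)[1:3]) {
    b <- blocks[[g]][, ss$sample_id]
    grp <- as.character(ss$haplotype_group)
    mult_ll <- function(cols) {
      m <- b[, cols, drop = FALSE]
      p <- rowSums(m) / sum(m)
      sum(m * log(p))
    }
    lr_mult <- 2 * ((mult_ll(grp == "FC") + mult_ll(grp == "VS")) -
                      mult_ll(rep(TRUE, ncol(b))))
    ff <- fit_dm(b, Xf); fr <- fit_dm(b, Xr)
    lr_dm <- 2 * (ff$loglik - fr$loglik)
    expect_equal(lr_dm, lr_mult, tolerance = 0.02)
  }
})
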