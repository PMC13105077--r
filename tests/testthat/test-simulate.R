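# Cohort, count and gene-set generators: determinism, design arithmetic,
# and recovery of the planted truth.

test_that("cohort size is the product of design cells and groups derive dominantly", {
  d <- cohort_design(n_per_cell = 1, genotypes = kl_genotypes,
                     ages = c("4mo", "12mo"), sexes = c("F", "M"),
                     n_batches = 2, seed = 1)
  s <- simulate_cohort(d)
  expect_equal(nrow(s), 1 * 5 * 2 * 2)
  expect_equal(anyDuplicated(s$sample_id), 0L)
  expect_equal(as.character(s$haplotype_group),
               as.character(haplotype_group(s$genotype)))
})

test_that("per-cell size tables give haplotype-group sizes equal to their cell sums", {
  # 12-month-style cohort with unequal cells; expected group sizes computed
  # by direct summation over the design before generation
  cells <- expand.grid(genotype = kl_genotypes, sex = c("F", "M"),
                       age_cohort = "12mo", stringsAsFactors = FALSE)
  cells$n <- c(10, 4, 4, 5, 5, 9, 6, 6, 3, 6)
  expected <- tapply(cells$n, as.character(haplotype_group(cells$genotype)), sum)
  s <- simulate_cohort(cohort_design(n_per_cell = cells, ages = "12mo"))
  got <- table(as.character(s$haplotype_group))
  expect_equal(as.integer(got[names(expected)]), as.integer(expected))
  expect_equal(nrow(s), sum(cells$n))
})

test_that("identical seeds give identical outputs for every simulator", {
  s <- tiny_cohort(2)
  expect_identical(tiny_cohort(2), tiny_cohort(2))
  gs <- simulate_gene_sets(sprintf("g%03d", 1:300), seed = 7)
  expect_identical(gs, simulate_gene_sets(sprintf("g%03d", 1:300), seed = 7))
  c1 <- simulate_counts(s, n_genes = 50, seed = 3)
  c2 <- simulate_counts(s, n_genes = 50, seed = 3)
  expect_identical(c1, c2)
  e1 <- simulate_exon_counts(s, n_genes = 5, seed = 4)
  expect_identical(e1, simulate_exon_counts(s, n_genes = 5, seed = 4))
})

test_that("invalid designs and truth are rejected", {
  expect_error(cohort_design(genotypes = character(0)), "non-empty")
  expect_error(cohort_design(n_per_cell = 0), "invalid design")
  s <- tiny_cohort(2)
  expect_error(simulate_counts(s, nb_dispersion = -1), "nb_dispersion")
  gs <- gene_set_collection(list(A = c("g1", "g2")))
  expect_error(
    simulate_counts(s, gs, list(effect_truth("missing", 1)), n_genes = 10),
    "unknown set")
})

test_that("planted set effects are recovered against the generator's own mean formula", {
  # delta = +1 SD, age-restricted: standardized VS-FC set-mean difference in
  # the old cohort should match delta; the young cohort should show ~0
  s <- simulate_cohort(cohort_design(n_per_cell = 5, ages = c("4mo", "12mo"),
                                     n_batches = 2, seed = 1))
  genes <- sprintf("sg%02d", 1:25)
  gs <- gene_set_collection(list(target = genes))
  delta <- 1
  reps <- 50
  diffs_old <- diffs_young <- numeric(reps)
  for (r in seq_len(reps)) {
    # the affected set is a small fraction of the transcriptome, as in real
    # data, so median-of-ratios factors are not distorted by the shift
    cm <- simulate_counts(s, gs, list(effect_truth("target", delta,
                                                   age_restricted = TRUE)),
                          n_genes = 400, nb_dispersion = 0.05,
                          batch_sd = 0.2, seed = 1000 + r)
    expr <- residualize(vst(cm), s, "batch")
    for (age in c("12mo", "4mo")) {
      ids <- s$sample_id[s$age_cohort == age]
      m <- set_mean_expression(expr[, ids], genes)
      hap <- s$haplotype_group[match(ids, s$sample_id)]
      d <- mean(m[hap == "VS"]) - mean(m[hap == "FC"])
      if (age == "12mo") diffs_old[r] <- d else diffs_young[r] <- d
    }
  }
  sigma <- attr(simulate_counts(s, gs, list(effect_truth("target", delta)),
                                n_genes = 400, seed = 1), "sigma_set")[["target"]]
  std_old <- diffs_old / sigma
  se <- sd(std_old) / sqrt(reps)
  expect_lt(abs(mean(std_old) - delta), 3 * se)
  expect_lt(abs(mean(diffs_young / sigma)), 3 * sd(diffs_young / sigma) / sqrt(reps))
})

test_that("empty truth yields nominal haplotype-term rejection rates", {
  s <- tiny_cohort(5)
  cm <- simulate_counts(s, n_genes = 800, seed = 6, include_sex_markers = FALSE)
  expr <- residualize(vst(cm), s, "batch")
  ts <- fit_factorial(expr, s)
  rej <- mean(ts$p[ts$term == "haplotype"] <= 0.05)
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("sex markers are deterministic and sex-specific", {
  s <- tiny_cohort(3)
  cm <- simulate_counts(s, n_genes = 30, seed = 2)
  mk <- sex_marker_spec()
  expect_true(all(c(mk$female, mk$male) %in% rownames(cm)))
  f <- s$sex == "F"
  expect_true(all(cm[mk$female, f] > 0) && all(cm[mk$female, !f] == 0))
  expect_true(all(cm[mk$male[1], !f] > 0) && all(cm[mk$male[1], f] == 0))
})

test_that("synthetic pathway/domain collections have intact hierarchy", {
  gs <- simulate_gene_sets(sprintf("g%04d", 1:2000), n_domains = 19,
                           subdomains_per_domain = 4, subdomain_size = 15,
                           seed = 5)
  bio <- gs$biodomains
  # 19 domains each with 4 subdomains, hierarchy resolvable
  expect_equal(length(bio$hierarchy), 19 * 4)
  expect_true(all(unname(bio$hierarchy) %in% names(bio$sets)))
  parents <- unique(unname(bio$hierarchy))
  expect_equal(length(parents), 19)
  # each domain set contains its subdomains' genes
  for (sub in names(bio$hierarchy)[1:5])
    expect_true(all(bio$sets[[sub]] %in% bio$sets[[bio$hierarchy[[sub]]]]))
})
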