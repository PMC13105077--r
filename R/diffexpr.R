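# Per-gene factorial linear modeling of normalized expression on age, sex
# and haplotype with pairwise interactions, term-level partial F-tests, DEG
# counting, and the dominant-vs-additive genotype-coding comparison.

# Residual sums of squares of Y (samples x genes) on design X, via one QR.
.rss <- function(X, Y) {
  r <- qr.resid(qr(X), Y)
  colSums(r^2)
}

# Term labels for the factorial model.
.factorial_terms <- function(include_age) {
  if (include_age)
    c("age", "sex", "haplotype", "age:sex", "age:haplotype", "sex:haplotype")
  else c("sex", "haplotype", "sex:haplotype")
}

#' Per-gene factorial model of age, sex and haplotype
#'
#' Fits, for every gene, ordinary least squares of normalized expression on
#' age, sex and the 3-level haplotype group with all pairwise interactions
#' (`y = b1 age + b2 sex + b3 haplotype + b12 + b13 + b23 + e`). Each term is
#' tested with a partial F-test respecting marginality (type-II style): a
#' main effect is tested against a model retaining the other main effects
#' and all interactions not involving it; an interaction is tested against
#' the full model without it. P-values are BH-adjusted within each term
#' across genes. When the samples span a single age cohort the age terms are
#' dropped from the model.
#'
#' @param expr expression matrix, genes x samples.
#' @param samples sample table matched to `expr` by `sample_id`.
#' @param include_age force age terms in or out; default: include iff more
#'   than one age cohort is present.
#' @return data.frame of class `term_stats`: `gene_id`, `term`, `F`, `p`,
#'   `q`; attribute `reference_levels` records the (alphabetical) reference
#'   level of each factor.
#' @export
fit_factorial <- function(expr, samples, include_age = NULL) {
  samples <- .align_samples(expr, samples)
  age <- factor(as.character(samples$age_cohort))
  sex <- factor(as.character(samples$sex))
  hap <- factor(as.character(samples$haplotype_group),
                levels = c("FC", "WT", "VS"))
  hap <- droplevels(hap)
  include_age <- include_age %||% (nlevels(age) > 1)
  fac <- list(sex = sex, haplotype = hap)
  if (include_age) fac <- c(list(age = age), fac)
  for (nm in names(fac)) {
    cnt <- table(fac[[nm]])
    if (any(cnt == 0)) .stop("empty level in factor '", nm, "'")
    if (any(cnt < 2)) .stop("factor '", nm, "' has a level with < 2 samples")
  }
  dat <- as.data.frame(fac)
  form <- if (include_age)
    ~ age * sex + age * haplotype + sex * haplotype else ~ sex * haplotype
  X <- stats::model.matrix(form, dat)
  if (qr(X)$rank < ncol(X)) {
    piv <- qr(X)$pivot
    aliased <- colnames(X)[piv[(qr(X)$rank + 1):ncol(X)]]
    .stop("collinear design; aliased column(s): ",
          paste(aliased, collapse = ", "))
  }
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  # normalize interaction labels to the fixed order used in output
  canon <- function(l) {
    parts <- strsplit(l, ":")[[1]]
    paste(parts[order(match(parts, c("age", "sex", "haplotype")))], collapse = ":")
  }
  labels <- vapply(labels, canon, "")
  terms_out <- .factorial_terms(include_age)
  Y <- t(expr)
  n <- nrow(Y)
  out <- vector("list", length(terms_out))
  for (k in seq_along(terms_out)) {
    tm <- terms_out[[k]]
    involves <- function(l) tm %in% strsplit(l, ":")[[1]] || l == tm
    if (grepl(":", tm)) {
      full_lab <- labels
      red_lab <- setdiff(labels, tm)
    } else {
      full_lab <- labels[!vapply(labels, function(l)
        grepl(":", l) && involves(l), TRUE)]
      red_lab <- setdiff(full_lab, tm)
    }
    keep_full <- assign %in% c(0, match(full_lab, labels))
    keep_red <- assign %in% c(0, match(red_lab, labels))
    Xf <- X[, keep_full, drop = FALSE]
    Xr <- X[, keep_red, drop = FALSE]
    rss_f <- .rss(Xf, Y)
    rss_r <- .rss(Xr, Y)
    df1 <- ncol(Xf) - ncol(Xr)
    df2 <- n - ncol(Xf)
    eps <- 1e-12 * pmax(colSums(Y^2), 1)
    Fstat <- pmax(((rss_r - rss_f) / df1) / (rss_f / df2), 0)
    degenerate <- rss_f < eps
    Fstat[degenerate | !is.finite(Fstat)] <- 0
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    p[degenerate] <- 1
    out[[k]] <- data.frame(gene_id = rownames(expr), term = tm,
                           F = Fstat, p = p,
                           q = stats::p.adjust(p, method = "BH"),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reference_levels") <- vapply(fac, function(f) levels(f)[1], "")
  class(res) <- c("term_stats", "data.frame")
  res
}

#' Count differentially expressed genes per model term
#'
#' @param stats `term_stats` from [fit_factorial()].
#' @param fdr BH q-value threshold (default 0.05).
#' @return named integer vector, term -> number of genes with `q <= fdr`.
#' @export
count_deg <- function(stats, fdr = 0.05) {
  if (!nrow(stats)) .stop("empty term_stats")
  tab <- tapply(stats$q <= fdr, stats$term, sum)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[unique(stats$term)]
}

#' Compare dominant and additive genotype codings for a gene set
#'
#' Fits the set's mean expression on (a) the dominant carrier grouping
#' FC < WT < VS as a single ordered predictor (-1, 0, +1) and (b) the
#' additive allele dosage along the VS-vs-FC axis (FC/FC = -2, WT/FC = -1,
#' WT/WT = 0, WT/VS = +1, VS/VS = +2), and reports adjusted variance
#' explained for each.
#'
#' @param expr expression matrix.
#' @param samples sample table with a 5-level `genotype` column.
#' @param genes gene ids of the set.
#' @return named numeric vector `c(dominant_R2, additive_R2)`.
#' @export
compare_codings <- function(expr, samples, genes) {
  samples <- .align_samples(expr, samples)
  y <- set_mean_expression(expr, genes, set_name = "coding-comparison set")
  present <- unique(as.character(samples$genotype))
  absent <- setdiff(kl_genotypes, present)
  if (length(absent))
    warning("genotype class(es) absent: ", paste(absent, collapse = ", "),
            "; proceeding with remaining classes")
  dom <- c("WT/WT" = 0, "WT/FC" = -1, "FC/FC" = -1, "WT/VS" = 1, "VS/VS" = 1)
  add <- c("FC/FC" = -2, "WT/FC" = -1, "WT/WT" = 0, "WT/VS" = 1, "VS/VS" = 2)
  g <- as.character(samples$genotype)
  r2 <- function(x) summary(stats::lm(y ~ x))$adj.r.squared
  c(dominant_R2 = r2(dom[g]), additive_R2 = r2(add[g]))
}
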