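# Dirichlet-multinomial (DM) differential exon/transcript usage between FC
# and VS carriers with batch and sex covariates.
#
# Model: counts x_i | total n_i ~ DM(n_i, p_i, gamma) with logit-linear
# proportions p_i = softmax(B z_i) (last feature as reference) and a
# per-gene precision gamma. Genes are tested by likelihood ratio of the
# design with vs without the genotype column, df = (K - 1).

#' Apply the expression filters to an exon count table
#'
#' Keeps features expressed (count above `expressed_threshold`, default 0)
#' in at least `min_samples` samples and with mean count across samples of
#' at least `min_mean`; genes left with fewer than 2 features are dropped.
#' Both boundary comparisons are inclusive.
#'
#' @param table `exon_count_table`.
#' @param min_samples minimum samples in which a feature must be expressed
#'   (default 10).
#' @param min_mean minimum mean count across samples (default 10).
#' @param expressed_threshold a feature counts as expressed in a sample when
#'   its count exceeds this value (default 0).
#' @return filtered `exon_count_table`.
#' @export
filter_features <- function(table, min_samples = 10, min_mean = 10,
                            expressed_threshold = 0) {
  samp_cols <- setdiff(names(table), c("gene_id", "feature_id"))
  m <- as.matrix(table[, samp_cols, drop = FALSE])
  keep <- rowSums(m > expressed_threshold) >= min_samples &
    rowMeans(m) >= min_mean
  out <- table[keep, , drop = FALSE]
  n_feat <- table(out$gene_id)
  out <- out[out$gene_id %in% names(n_feat)[n_feat >= 2], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exon_count_table", "data.frame")
  out
}

#' Dirichlet-multinomial log pmf
#'
#' Log probability of a feature count vector under DM sampling, including
#' the multinomial coefficient. `gamma = Inf` gives the multinomial limit.
#' A zero proportion with a positive count yields `-Inf`.
#'
#' @param counts nonnegative integer vector (one gene, one sample).
#' @param proportions probability vector on the simplex.
#' @param gamma precision (> 0, possibly `Inf`).
#' @export
dm_loglik <- function(counts, proportions, gamma) {
  if (length(counts) != length(proportions))
    .stop("counts and proportions must have equal length")
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    .stop("proportions must lie on the simplex")
  if (gamma <= 0) .stop("gamma must be > 0")
  if (any(counts < 0)) .stop("counts must be nonnegative")
  K <- length(counts)
  if (K == 1L) return(0)
  n <- sum(counts)
  if (any(proportions == 0 & counts > 0)) return(-Inf)
  coef <- lgamma(n + 1) - sum(lgamma(counts + 1))
  if (!is.finite(gamma)) {
    pos <- counts > 0
    return(coef + sum(counts[pos] * log(proportions[pos])))
  }
  a <- gamma * proportions
  coef + lgamma(gamma) - lgamma(n + gamma) +
    sum(lgamma(counts + a) - lgamma(a))
}

# Vectorized negative log-likelihood and gradient over a block.
# counts: K x n; Z: n x pz design; par = c(vec(B[K-1, pz]), log gamma).
.dm_nll <- function(par, counts, Z) {
  K <- nrow(counts); n <- ncol(counts); pz <- ncol(Z)
  B <- matrix(par[seq_len((K - 1) * pz)], K - 1, pz)
  g <- exp(par[length(par)])
  eta <- rbind(B %*% t(Z), 0)                      # K x n
  eta <- sweep(eta, 2, apply(eta, 2, max))
  P <- exp(eta); P <- sweep(P, 2, colSums(P), "/")
  A <- g * P
  tot <- colSums(counts)
  ll <- sum(lgamma(g) - lgamma(tot + g)) +
    sum(lgamma(counts + A) - lgamma(A))
  -ll
}

.dm_nll_grad <- function(par, counts, Z) {
  K <- nrow(counts); n <- ncol(counts); pz <- ncol(Z)
  B <- matrix(par[seq_len((K - 1) * pz)], K - 1, pz)
  g <- exp(par[length(par)])
  eta <- rbind(B %*% t(Z), 0)
  eta <- sweep(eta, 2, apply(eta, 2, max))
  P <- exp(eta); P <- sweep(P, 2, colSums(P), "/")
  A <- g * P
  tot <- colSums(counts)
  D <- digamma(counts + A) - digamma(A)            # K x n
  dp <- colSums(D * P)                             # sum_k d_k p_k, per sample
  # d ll / d eta_j = g * p_j * (d_j - sum_k d_k p_k), j = 1..K-1
  Geta <- g * P[-K, , drop = FALSE] *
    sweep(D[-K, , drop = FALSE], 2, dp)            # (K-1) x n
  GB <- Geta %*% Z                                 # (K-1) x pz
  dg <- sum(digamma(g) - digamma(tot + g) + dp) * g
  -c(as.numeric(GB), dg)
}

#' Fit the DM regression model to one gene block
#'
#' Maximizes the DM log-likelihood over the logit-linear proportion
#' coefficients and log-precision, multi-starting from (a) pooled observed
#' proportions and (b) uniform proportions. Convergence requires the
#' optimizer to report success or a scaled gradient norm below 1e-6.
#'
#' @param block feature x sample count matrix (>= 2 features).
#' @param design numeric design matrix (samples x covariate columns,
#'   including the intercept); must be full rank.
#' @return list of class `dm_fit`: `coef` ((K-1) x p matrix), `gamma`,
#'   `loglik` (including the multinomial coefficient), `converged`,
#'   `fitted_proportions` (K x n).
#' @export
fit_dm <- function(block, design) {
  block <- as.matrix(block)
  K <- nrow(block)
  if (K < 2) .stop("block must have >= 2 features")
  Z <- as.matrix(design)
  if (qr(Z)$rank < ncol(Z)) .stop("design is rank deficient")
  pz <- ncol(Z)
  pooled <- rowSums(block) + 0.5
  pooled <- pooled / sum(pooled)
  b0 <- log(pooled[-K] / pooled[K])
  start_pooled <- c(as.numeric(cbind(b0, matrix(0, K - 1, pz - 1))), log(30))
  start_unif <- c(rep(0, (K - 1) * pz), log(30))
  best <- NULL
  # log-gamma is capped at log(1e8): beyond that the DM is multinomial to
  # far below statistical precision, while lgamma differences lose all
  # floating-point accuracy; coefficients are boxed to keep softmax finite.
  lower <- c(rep(-30, (K - 1) * pz), log(1e-3))
  upper <- c(rep(30, (K - 1) * pz), log(1e8))
  for (st in list(start_pooled, start_unif)) {
    fit <- tryCatch(
      stats::optim(st, .dm_nll, .dm_nll_grad, counts = block, Z = Z,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    gnorm <- sqrt(sum(.dm_nll_grad(fit$par, block, Z)^2))
    ok <- fit$convergence == 0 || gnorm < 1e-6 * (1 + abs(fit$value))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (ok && !best$ok && fit$value < best$value + 1e-6)) {
      best <- list(par = fit$par, value = fit$value, ok = ok)
    }
  }
  if (is.null(best)) return(structure(list(converged = FALSE), class = "dm_fit"))
  par <- best$par
  B <- matrix(par[seq_len((K - 1) * pz)], K - 1, pz,
              dimnames = list(rownames(block)[-K], colnames(Z)))
  eta <- rbind(B %*% t(Z), 0)
  eta <- sweep(eta, 2, apply(eta, 2, max))
  P <- exp(eta); P <- sweep(P, 2, colSums(P), "/")
  dimnames(P) <- dimnames(block)
  mult_coef <- sum(lgamma(colSums(block) + 1)) - sum(lgamma(block + 1))
  structure(list(coef = B, gamma = exp(par[length(par)]),
                 loglik = -best$value + mult_coef,
                 converged = best$ok, fitted_proportions = P),
            class = "dm_fit")
}

#' Likelihood-ratio test of differential usage between FC and VS carriers
#'
#' WT samples are excluded. For each gene block the full design (intercept +
#' covariates + genotype) is compared with the reduced design without
#' genotype; the LR statistic, rescaled by the first-order Bartlett-type
#' factor `(n - p) / n` (n = samples tested, p = full-design columns) to
#' correct the small-sample inflation of the likelihood ratio, is referred
#' to a chi-square with `(K - 1)` degrees of freedom (one genotype column).
#' P-values are BH-adjusted across testable genes; genes failing to converge
#' under either design are flagged and excluded from the family.
#'
#' @param table filtered `exon_count_table` (see [filter_features()]).
#' @param samples sample table.
#' @param covariates sample-table columns used as additive covariates
#'   (default batch and sex).
#' @return data.frame of class `dtu_result`: `gene_id`, `n_features`, `LR`,
#'   `df`, `p`, `p_adj`, `converged`.
#' @export
dtu_test <- function(table, samples, covariates = c("batch", "sex")) {
  samples <- .check_samples(samples)
  keep <- samples$haplotype_group %in% c("FC", "VS")
  samples <- samples[keep, , drop = FALSE]
  grp <- table(droplevels(samples$haplotype_group))
  if (length(grp) < 2 || any(grp < 3))
    .stop("need >= 3 samples in each of the FC and VS groups")
  samp_cols <- setdiff(names(table), c("gene_id", "feature_id"))
  if (!all(samples$sample_id %in% samp_cols))
    .stop("exon table is missing sample column(s)")
  blocks <- exon_blocks(table)
  blocks <- lapply(blocks, function(b) b[, samples$sample_id, drop = FALSE])
  covs <- lapply(samples[covariates], function(x) factor(as.character(x)))
  dat <- data.frame(covs, genotype = factor(as.character(samples$haplotype_group),
                                            levels = c("FC", "VS")))
  Xfull <- stats::model.matrix(~ ., dat)
  Xred <- stats::model.matrix(~ ., dat[, covariates, drop = FALSE])
  res <- lapply(names(blocks), function(g) {
    b <- blocks[[g]]
    ff <- fit_dm(b, Xfull)
    fr <- fit_dm(b, Xred)
    if (!isTRUE(ff$converged) || !isTRUE(fr$converged))
      return(data.frame(gene_id = g, n_features = nrow(b), LR = NA_real_,
                        df = NA_integer_, p = NA_real_, converged = FALSE))
    LR <- max(2 * (ff$loglik - fr$loglik), 0) *
      (nrow(Xfull) - ncol(Xfull)) / nrow(Xfull)
    df <- (nrow(b) - 1L) * 1L
    data.frame(gene_id = g, n_features = nrow(b), LR = LR, df = df,
               p = stats::pchisq(LR, df, lower.tail = FALSE),
               converged = TRUE)
  })
  out <- do.call(rbind, res)
  if (any(!out$converged))
    warning(sum(!out$converged), " gene(s) failed to converge; excluded from testing")
  out$p_adj <- NA_real_
  out$p_adj[out$converged] <- stats::p.adjust(out$p[out$converged], method = "BH")
  rownames(out) <- NULL
  class(out) <- c("dtu_result", "data.frame")
  out
}
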