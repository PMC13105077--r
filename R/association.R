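# Ordered-haplotype trend model on gene-set mean expression, FDR screening,
# and the pathway-by-domain biadjacency matrix of effect coefficients.

# Closed-form simple linear regression of each row of Y on x; returns beta,
# adjusted R^2 and the two-sided p for the slope. A quadratic-contrast
# diagnostic coefficient is returned alongside but never tested.
.trend_core <- function(Y, x, xq = NULL) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- rowMeans(Y)
  Yc <- Y - ym
  beta <- as.numeric(Yc %*% xc) / sxx
  fitted_dev <- outer(beta, xc)
  rss <- rowSums((Yc - fitted_dev)^2)
  tss <- rowSums(Yc^2)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- ifelse(se > 0, beta / se, 0)
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  zerovar <- tss < 1e-24
  if (any(zerovar)) {
    beta[zerovar] <- 0; p[zerovar] <- 1; r2_adj[zerovar] <- 0
  }
  beta_quad <- if (!is.null(xq)) {
    xqc <- xq - mean(xq)
    as.numeric(Yc %*% xqc) / sum(xqc^2)
  } else rep(NA_real_, nrow(Y))
  data.frame(beta = unname(beta), r2_adj = unname(r2_adj), p = unname(p),
             beta_quad = unname(beta_quad), zero_variance = unname(zerovar),
             row.names = NULL)
}

# Centered linear contrast codes for the ordered haplotype factor.
.hap_contrast <- function(hap) {
  codes <- c(FC = -1, WT = 0, VS = 1)
  codes[as.character(hap)]
}

#' Fit the ordered-haplotype trend model to one set's mean expression
#'
#' OLS of per-sample set-mean expression on the centered linear contrast of
#' the ordered haplotype factor FC < WT < VS (codes -1, 0, +1). A positive
#' coefficient means higher fitted expression in VS than FC carriers.
#' Variance explained is adjusted R^2 (which may be negative). The quadratic
#' contrast coefficient is computed as a linearity diagnostic (column
#' `beta_quad`) but never tested.
#'
#' @param set_mean numeric vector of per-sample set means, named by
#'   sample id or aligned to `samples` rows.
#' @param samples sample table with `haplotype_group`.
#' @param set_id label carried into the result.
#' @return one-row data.frame: `set_id`, `n_FC`, `n_WT`, `n_VS`, `beta`,
#'   `r2_adj`, `p`, `beta_quad`.
#' @export
fit_haplotype_trend <- function(set_mean, samples, set_id = NA_character_) {
  samples <- .check_samples(samples)
  if (!is.null(names(set_mean))) {
    idx <- match(names(set_mean), samples$sample_id)
    if (anyNA(idx)) .stop("set_mean names not all present in sample table")
    samples <- samples[idx, , drop = FALSE]
  } else if (length(set_mean) != nrow(samples))
    .stop("set_mean length does not match sample table")
  fits <- fit_trend_sets(matrix(set_mean, nrow = 1,
                                dimnames = list(set_id, NULL)), samples)
  fits$set_id <- set_id
  fits
}

#' Fit the trend model to every row of a set-means matrix
#'
#' @param set_means sets x samples matrix (e.g. from [set_means_matrix()]).
#' @param samples sample table aligned to the columns (by `sample_id` when
#'   column names are present).
#' @return data.frame, one row per set: `set_id`, group sizes, `beta`,
#'   `r2_adj`, `p`, `beta_quad`. Zero-variance responses get `beta = 0`,
#'   `p = 1` with a message.
#' @export
fit_trend_sets <- function(set_means, samples) {
  samples <- .check_samples(samples)
  if (!is.null(colnames(set_means))) {
    if (!setequal(colnames(set_means), samples$sample_id))
      .stop("set_means samples and metadata sample_ids do not match")
    samples <- samples[match(colnames(set_means), samples$sample_id), ,
                       drop = FALSE]
  } else if (ncol(set_means) != nrow(samples))
    .stop("set_means columns do not match sample table")
  cnt <- table(factor(samples$haplotype_group, levels = c("FC", "WT", "VS")))
  if (any(cnt == 0))
    .stop("haplotype group(s) absent: ",
          paste(names(cnt)[cnt == 0], collapse = ", "))
  if (any(cnt < 2))
    .stop("need >= 2 samples in each haplotype group")
  x <- .hap_contrast(samples$haplotype_group)
  xq <- c(FC = 1, WT = -2, VS = 1)[as.character(samples$haplotype_group)]
  core <- .trend_core(as.matrix(set_means), x, xq)
  if (any(core$zero_variance))
    message(sum(core$zero_variance), " set(s) had zero response variance; beta = 0, p = 1")
  data.frame(set_id = rownames(set_means) %||%
               sprintf("set%03d", seq_len(nrow(set_means))),
             n_FC = unname(cnt["FC"]), n_WT = unname(cnt["WT"]),
             n_VS = unname(cnt["VS"]),
             beta = core$beta, r2_adj = core$r2_adj, p = core$p,
             beta_quad = core$beta_quad,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen trend fits by FDR and sort by effect
#'
#' BH adjustment across the supplied family (subdomains, Biodomains and
#' intersections are distinct families with their own thresholds: 0.05 for
#' subdomains, 0.001 for intersections). Retained rows are sorted by `beta`
#' descending.
#'
#' @param fits data.frame from [fit_trend_sets()] (or rbind of
#'   [fit_haplotype_trend()] rows).
#' @param fdr q-value threshold.
#' @return the retained rows with a `q` column, sorted by `beta` descending.
#' @export
screen_sets <- function(fits, fdr = 0.001) {
  if (!nrow(fits)) .stop("empty fits")
  fits$q <- stats::p.adjust(fits$p, method = "BH")
  out <- fits[fits$q <= fdr, , drop = FALSE]
  out[order(-out$beta), , drop = FALSE]
}

#' Pathway-by-domain biadjacency matrix of effect coefficients
#'
#' @param results screened trend fits over intersection sets; needs columns
#'   `pathway`, `domain`, `beta` (a `set_id` of the form
#'   `"<pathway> :: <domain>"` is split when the columns are absent).
#' @return numeric matrix, rows = pathways, columns = domains, cells = beta
#'   (NA where the pair was not retained); rows and columns ordered by mean
#'   absolute beta, descending.
#' @export
biadjacency <- function(results) {
  if (!nrow(results)) return(matrix(numeric(0), 0, 0))
  if (!all(c("pathway", "domain") %in% names(results))) {
    parts <- strsplit(results$set_id, " :: ", fixed = TRUE)
    results$pathway <- vapply(parts, `[[`, "", 1)
    results$domain <- vapply(parts, `[[`, "", 2)
  }
  key <- paste(results$pathway, results$domain)
  if (anyDuplicated(key))
    .stop("duplicate (pathway, domain) entries: ",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  paths <- unique(results$pathway)
  doms <- unique(results$domain)
  m <- matrix(NA_real_, length(paths), length(doms),
              dimnames = list(paths, doms))
  m[cbind(match(results$pathway, paths), match(results$domain, doms))] <-
    results$beta
  row_ord <- order(-apply(abs(m), 1, mean, na.rm = TRUE))
  col_ord <- order(-apply(abs(m), 2, mean, na.rm = TRUE))
  m[row_ord, col_ord, drop = FALSE]
}

#' Write a biadjacency matrix as TSV with explicit missing markers
#'
#' @param mat matrix from [biadjacency()].
#' @param path output path; absent pairs are written as `NA`.
#' @export
write_biadjacency <- function(mat, path) {
  df <- data.frame(pathway = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
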