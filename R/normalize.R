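# Normalization: median-of-ratios size factors, a variance-stabilizing
# log transform, covariate residualization, and marker-based sex validation.

#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed as the median across reference genes of
#' the ratio of a sample's count to the gene's geometric mean, then centered
#' so the factors have geometric mean 1. Reference genes are those expressed
#' in every sample; if none exist, genes nonzero in at least half the samples
#' are used instead (geometric means and medians over their positive counts
#' only) with a warning.
#'
#' @param counts nonnegative matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stop("counts must be nonnegative")
  if (any(colSums(counts > 0) < 1))
    .stop("every sample must have at least one nonzero count")
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    warning("no gene expressed in all samples; falling back to genes nonzero in >= 50% of samples")
    ref <- rowMeans(counts > 0) >= 0.5
    if (!any(ref)) .stop("no usable reference genes for size factors")
    sub <- counts[ref, , drop = FALSE]
    geo <- apply(sub, 1, function(r) exp(mean(log(r[r > 0]))))
    f <- apply(sub, 2, function(cl) {
      ok <- cl > 0
      stats::median(cl[ok] / geo[ok])
    })
  } else {
    sub <- counts[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    f <- apply(sub, 2, function(cl) stats::median(cl / geo))
  }
  sf <- f / exp(mean(log(f)))
  names(sf) <- colnames(counts)
  sf
}

#' Variance-stabilizing transform of scaled counts
#'
#' `log2(count / factor + pseudocount)`. The transform is monotone in counts
#' and, for overdispersed counts, makes the per-gene SD approximately
#' independent of the mean. Provenance (pseudocount, factor method,
#' covariates regressed out) is carried in attributes.
#'
#' @param counts nonnegative matrix, genes x samples.
#' @param factors size factors; computed by [size_factors()] when NULL.
#' @param pseudocount added inside the log (default 1).
#' @return numeric matrix of class `expression_matrix` with attributes
#'   `residualized` (character vector of removed covariates) and
#'   `provenance`.
#' @export
vst <- function(counts, factors = NULL, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) .stop("counts must be nonnegative")
  if (is.null(factors)) factors <- size_factors(counts)
  if (length(factors) != ncol(counts) || any(factors <= 0))
    .stop("factors must be positive, one per sample")
  expr <- log2(sweep(counts, 2, factors, "/") + pseudocount)
  structure(expr, class = c("expression_matrix", class(expr)),
            residualized = character(0),
            provenance = list(pseudocount = pseudocount,
                              factor_method = "median-of-ratios"))
}

#' Regress covariates out of an expression matrix
#'
#' Per gene, ordinary least squares on the covariates' indicator columns; the
#' residuals are returned with the gene's grand mean added back so set means
#' stay interpretable on the normalized scale. The operation is idempotent
#' and leaves genes orthogonal to the covariates unchanged.
#'
#' @param expr expression matrix (genes x samples) from [vst()].
#' @param samples sample table; matched to `expr` columns by `sample_id`.
#' @param covariates ordered character vector of sample-table columns to
#'   remove (e.g. `"batch"`, then later `"sex"`).
#' @return expression matrix with updated `residualized` attribute.
#' @export
residualize <- function(expr, samples, covariates) {
  samples <- .align_samples(expr, samples)
  for (cv in covariates) {
    if (!cv %in% names(samples)) .stop("unknown covariate: ", cv)
    lev <- table(as.character(samples[[cv]]))
    if (length(lev) < 2)
      .stop("covariate '", cv, "' has a single level; nothing to remove ",
            "(all samples in one level)")
  }
  X <- stats::model.matrix(~ ., data = as.data.frame(
    lapply(samples[covariates], function(x) factor(as.character(x)))))
  qr_x <- qr(X)
  res <- t(qr.resid(qr_x, t(expr)))
  res <- res + rowMeans(expr)
  attrs <- attributes(expr)
  structure(res, class = attrs$class %||% class(res),
            dimnames = dimnames(expr),
            residualized = unique(c(attr(expr, "residualized"), covariates)),
            provenance = attr(expr, "provenance"))
}

#' Validate annotated sex against marker-gene expression
#'
#' Sex is inferred from normalized marker expression: the female marker high
#' and male markers near zero imply F, the reverse implies M. "High" is
#' relative to the midpoint of the two sex-wise medians for each marker.
#' Samples whose inferred sex contradicts the annotation fail.
#'
#' @param counts counts matrix containing the marker genes.
#' @param samples sample table with annotated `sex`.
#' @param marker_spec list with elements `female` (one gene id) and `male`
#'   (one or more gene ids); defaults to [sex_marker_spec()].
#' @return data.frame with `sample_id`, `annotated`, `inferred`, `pass`.
#' @export
validate_sex <- function(counts, samples, marker_spec = sex_marker_spec()) {
  samples <- .align_samples(counts, samples)
  markers <- c(marker_spec$female, marker_spec$male)
  missing <- setdiff(markers, rownames(counts))
  if (length(missing))
    .stop("marker gene(s) absent from counts: ", paste(missing, collapse = ", "))
  if (length(marker_spec$female) != 1L || length(marker_spec$male) < 1L)
    .stop("marker_spec needs one female marker and >= 1 male markers")
  sf <- size_factors(counts)
  norm <- log2(sweep(counts[markers, , drop = FALSE], 2, sf, "/") + 1)
  is_f <- samples$sex == "F"
  midpoint <- apply(norm, 1, function(r)
    (stats::median(r[is_f]) + stats::median(r[!is_f])) / 2)
  high <- norm > midpoint
  fem_high <- high[marker_spec$female, ]
  male_high <- colMeans(high[marker_spec$male, , drop = FALSE]) > 0.5
  inferred <- ifelse(fem_high & !male_high, "F",
                     ifelse(!fem_high & male_high, "M", NA))
  data.frame(sample_id = samples$sample_id,
             annotated = samples$sex,
             inferred = inferred,
             pass = !is.na(inferred) & inferred == samples$sex,
             stringsAsFactors = FALSE)
}
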