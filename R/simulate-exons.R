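# Dirichlet-multinomial exon/feature count simulation with known usage truth.

#' Declare a planted differential-usage effect
#'
#' @param gene_id gene receiving the shift.
#' @param shifted_feature_index which feature's usage proportion is shifted.
#' @param proportion_shift signed change in that feature's usage proportion
#'   between FC and VS carriers (applied to VS; remaining features are
#'   rescaled). Shifts that would push any proportion off the simplex are
#'   rejected at generation time, never silently clipped.
#' @param precision Dirichlet-multinomial precision gamma (> 0); larger
#'   values approach pure multinomial sampling.
#' @export
dtu_truth <- function(gene_id, shifted_feature_index, proportion_shift,
                      precision = 50) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            .is_count(shifted_feature_index),
            is.numeric(proportion_shift), length(proportion_shift) == 1L)
  if (precision <= 0) .stop("precision must be > 0")
  structure(list(gene_id = gene_id,
                 shifted_feature_index = as.integer(shifted_feature_index),
                 proportion_shift = proportion_shift, precision = precision),
            class = "dtu_truth")
}

# Apply a usage shift to a proportion vector; errors if it leaves the simplex.
.shift_proportions <- function(p, index, shift) {
  if (index > length(p)) .stop("shifted_feature_index exceeds feature count")
  p_new <- p
  p_new[index] <- p[index] + shift
  if (p_new[index] <= 0 || p_new[index] >= 1)
    .stop("proportion_shift of ", shift, " pushes feature ", index,
          " off the simplex (baseline ", signif(p[index], 3), ")")
  p_new[-index] <- p[-index] * (1 - p_new[index]) / (1 - p[index])
  p_new
}

# One Dirichlet-multinomial draw per column of totals; gamma = Inf gives the
# multinomial limit.
.rdirmult <- function(totals, p, gamma) {
  K <- length(p)
  out <- matrix(0L, K, length(totals))
  for (j in seq_along(totals)) {
    pj <- if (is.finite(gamma)) {
      w <- rgamma(K, shape = gamma * p)
      if (sum(w) == 0) p else w / sum(w)
    } else p
    out[, j] <- rmultinom(1, totals[j], pj)
  }
  out
}

#' Simulate per-gene feature (exon/transcript) counts
#'
#' Per-gene totals are Poisson around `depth`; feature splits are
#' Dirichlet-multinomial with group-specific proportions for genes carrying a
#' [dtu_truth()]: FC and WT samples use the baseline proportions, VS samples
#' the shifted ones.
#'
#' @param samples cohort table from [simulate_cohort()].
#' @param truth list of [dtu_truth()] objects.
#' @param n_genes number of genes.
#' @param features_per_gene features per gene (>= 2 for any truth gene).
#' @param depth expected per-gene total count per sample.
#' @param precision default DM precision for genes without truth (`Inf` =
#'   multinomial).
#' @param seed integer seed.
#' @return an `exon_count_table`: data.frame with columns `gene_id`,
#'   `feature_id`, then one column per sample; attribute `truth_props` holds
#'   per-truth-gene baseline and shifted proportion vectors.
#' @export
simulate_exon_counts <- function(samples, truth = list(), n_genes = 20,
                                 features_per_gene = 3, depth = 500,
                                 precision = 50, seed = 1) {
  samples <- .check_samples(samples)
  if (inherits(truth, "dtu_truth")) truth <- list(truth)
  if (length(truth) && features_per_gene < 2)
    .stop("features_per_gene must be >= 2 for genes with usage truth")
  truth_ids <- vapply(truth, `[[`, "", "gene_id")
  .seed_rng(seed)
  genes <- sprintf("dgene%04d", seq_len(n_genes))
  extra <- setdiff(truth_ids, genes)
  if (length(extra)) genes[seq_along(extra)] <- extra
  n <- nrow(samples)
  K <- features_per_gene
  is_vs <- samples$haplotype_group == "VS"
  blocks <- vector("list", n_genes)
  truth_props <- list()
  for (g in seq_len(n_genes)) {
    w <- rgamma(K, shape = 5)
    p0 <- w / sum(w)
    t_idx <- match(genes[g], truth_ids)
    p_vs <- p0
    gam <- precision
    if (!is.na(t_idx)) {
      t <- truth[[t_idx]]
      p_vs <- .shift_proportions(p0, t$shifted_feature_index, t$proportion_shift)
      gam <- t$precision
      truth_props[[genes[g]]] <- list(baseline = p0, shifted = p_vs)
    }
    totals <- rpois(n, depth)
    cnt <- matrix(0L, K, n)
    if (any(!is_vs)) cnt[, !is_vs] <- .rdirmult(totals[!is_vs], p0, gam)
    if (any(is_vs))  cnt[, is_vs]  <- .rdirmult(totals[is_vs], p_vs, gam)
    blocks[[g]] <- cnt
  }
  out <- data.frame(gene_id = rep(genes, each = K),
                    feature_id = paste0(rep(genes, each = K), ".f",
                                        rep(seq_len(K), n_genes)),
                    stringsAsFactors = FALSE)
  mat <- do.call(rbind, blocks)
  colnames(mat) <- samples$sample_id
  out <- cbind(out, as.data.frame(mat))
  class(out) <- c("exon_count_table", "data.frame")
  attr(out, "truth_props") <- truth_props
  out
}

#' Split an exon count table into per-gene matrices
#'
#' @param table an `exon_count_table` (data.frame with `gene_id`,
#'   `feature_id`, sample columns).
#' @return named list of feature-by-sample integer matrices.
#' @export
exon_blocks <- function(table) {
  samp_cols <- setdiff(names(table), c("gene_id", "feature_id"))
  split_idx <- split(seq_len(nrow(table)), table$gene_id)
  split_idx <- split_idx[unique(table$gene_id)]  # keep input order
  lapply(split_idx, function(i) {
    m <- as.matrix(table[i, samp_cols, drop = FALSE])
    rownames(m) <- table$feature_id[i]
    m
  })
}
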