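# Cross-system comparison: mouse haplotype effect coefficients vs treatment
# effect coefficients from a two-group expression experiment, over the same
# intersection sets via an ortholog map.

#' Filter transcripts by total count
#'
#' Keeps rows whose total count across all samples is at least `min_total`.
#'
#' @param counts matrix, features x samples.
#' @param min_total threshold (default 10, inclusive).
#' @export
filter_transcripts <- function(counts, min_total = 10) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) warning("no transcripts pass the total-count filter")
  counts[keep, , drop = FALSE]
}

#' Reduce an ortholog table to strict one-to-one pairs
#'
#' Any gene appearing in more than one pair (on either side) is dropped
#' entirely, so no gene is double-counted in set means.
#'
#' @param orthologs data.frame with columns `gene_a`, `gene_b`.
#' @export
orthologs_one_to_one <- function(orthologs) {
  if (!all(c("gene_a", "gene_b") %in% names(orthologs)))
    .stop("ortholog table needs gene_a and gene_b columns")
  orthologs <- unique(orthologs[, c("gene_a", "gene_b")])
  ok <- !(orthologs$gene_a %in% orthologs$gene_a[duplicated(orthologs$gene_a)]) &
    !(orthologs$gene_b %in% orthologs$gene_b[duplicated(orthologs$gene_b)])
  orthologs[ok, , drop = FALSE]
}

#' Treatment effect coefficient for one intersection set
#'
#' Maps the set's genes through the ortholog table, averages each mapped
#' gene's expression across replicates within each treatment group, and
#' regresses the stacked per-gene group means on a centered treatment
#' indicator (untreated = -1/2, treated = +1/2), so the coefficient is the
#' mean treated-minus-untreated difference over the set. Setting
#' `average_replicates = FALSE` fits on the individual replicate values
#' instead.
#'
#' @param expr expression matrix of the two-group experiment (other-species
#'   ids).
#' @param treatment character/factor per column, two levels; the
#'   alphabetically second level is "treated" unless the levels are exactly
#'   `untreated`/`treated`.
#' @param genes mouse gene ids of the intersection set.
#' @param orthologs ortholog table (reduced to one-to-one pairs internally).
#' @param average_replicates average within groups before fitting (default).
#' @return the treatment coefficient, or `NA` with a warning when no set
#'   gene maps into the matrix.
#' @export
treatment_effect <- function(expr, treatment, genes, orthologs,
                             average_replicates = TRUE) {
  orthologs <- orthologs_one_to_one(orthologs)
  mapped <- orthologs$gene_b[match(genes, orthologs$gene_a)]
  mapped <- intersect(mapped[!is.na(mapped)], rownames(expr))
  if (!length(mapped)) {
    warning("no mapped orthologs present in the expression matrix; set skipped")
    return(NA_real_)
  }
  treatment <- as.character(treatment)
  lev <- sort(unique(treatment))
  if (length(lev) != 2) .stop("treatment must have exactly two levels")
  if (setequal(lev, c("treated", "untreated"))) lev <- c("untreated", "treated")
  if (any(table(treatment) < 2)) .stop("need >= 2 samples per treatment group")
  xcode <- ifelse(treatment == lev[2], 0.5, -0.5)
  sub <- expr[mapped, , drop = FALSE]
  if (average_replicates) {
    m_ctrl <- rowMeans(sub[, treatment == lev[1], drop = FALSE])
    m_trt <- rowMeans(sub[, treatment == lev[2], drop = FALSE])
    y <- c(m_ctrl, m_trt)
    x <- rep(c(-0.5, 0.5), each = length(mapped))
  } else {
    y <- as.numeric(t(sub))
    x <- rep(xcode, times = length(mapped))
  }
  unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Treatment effects for every intersection set
#'
#' @param expr,treatment,orthologs as in [treatment_effect()].
#' @param intersections `intersection_sets` table.
#' @return named numeric vector (intersection id -> beta; sets with no
#'   mapped genes are dropped with the warning from [treatment_effect()]).
#' @export
treatment_effects <- function(expr, treatment, intersections, orthologs) {
  out <- vapply(seq_len(nrow(intersections)), function(i)
    treatment_effect(expr, treatment, intersections$genes[[i]], orthologs),
    0)
  names(out) <- intersections$id
  out[!is.na(out)]
}

#' Compare mouse and other-system effect coefficients
#'
#' Spearman rank correlation of the two beta vectors over their shared sets
#' (rank-based, so invariant to monotone rescaling of either side), plus a
#' per-set concordance call: a set is `concordant` when both betas clear a
#' magnitude floor and share sign, `discordant` when both clear it with
#' opposite signs, otherwise `null`. The default floor for each vector is
#' the median absolute beta of its own family.
#'
#' @param mouse data.frame with `set_id` and `beta` (e.g. from
#'   [fit_trend_sets()]), or a named numeric vector.
#' @param other named numeric vector (set id -> treatment beta).
#' @param magnitude_floor optional length-2 numeric `c(mouse, other)` floor
#'   overriding the medians.
#' @return list: `rho`, `p`, `n`, and `comparison` (data.frame with
#'   `set_id`, `beta_mouse`, `beta_other`, `class`).
#' @export
compare_effects <- function(mouse, other, magnitude_floor = NULL) {
  if (is.data.frame(mouse)) {
    bm <- mouse$beta
    names(bm) <- mouse$set_id
  } else bm <- mouse
  shared <- intersect(names(bm), names(other))
  if (length(shared) < 3) .stop("fewer than 3 shared sets")
  bm <- bm[shared]; bo <- other[shared]
  ct <- suppressWarnings(stats::cor.test(bm, bo, method = "spearman",
                                         exact = length(shared) <= 10))
  floor_m <- if (!is.null(magnitude_floor)) magnitude_floor[1] else
    stats::median(abs(bm))
  floor_o <- if (!is.null(magnitude_floor)) magnitude_floor[2] else
    stats::median(abs(bo))
  pass <- abs(bm) >= floor_m & abs(bo) >= floor_o
  cls <- ifelse(pass & sign(bm) == sign(bo), "concordant",
                ifelse(pass, "discordant", "null"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared),
       comparison = data.frame(set_id = shared, beta_mouse = unname(bm),
                               beta_other = unname(bo), class = cls,
                               stringsAsFactors = FALSE))
}
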