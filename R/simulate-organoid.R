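# Paired "organoid" dataset: a two-group (treated vs untreated) expression
# experiment whose per-set treatment effects have controlled concordance with
# the mouse haplotype truth, used to exercise the cross-system comparison.

#' Simulate a treated/untreated organoid-style count matrix
#'
#' For each intersection set, genes are mapped through the ortholog table and
#' the treated group receives a log2 shift proportional to the mouse effect
#' for that set: same sign for `concordant` sets, opposite for `discordant`,
#' zero for `null`. Three replicates per group by default, matching the
#' source experiment's design.
#'
#' @param intersections an `intersection_sets` table (see
#'   [build_intersections()]).
#' @param concordance_spec named character vector, intersection id ->
#'   `"concordant"`, `"discordant"` or `"null"`; keys must be intersection
#'   ids.
#' @param mouse_truth named numeric vector, intersection id -> mouse
#'   standardized effect `delta` (sign and magnitude the organoid effects are
#'   tied to).
#' @param orthologs two-column ortholog data.frame (`gene_a` = mouse,
#'   `gene_b` = other species); reduced to one-to-one pairs.
#' @param n_replicates replicates per group.
#' @param effect_log2fc log2 shift applied per unit of `|delta|`.
#' @param n_background extra unaffected genes.
#' @param nb_dispersion NB dispersion of the counts.
#' @param base_log2_range baseline log2 mean range.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix, human-style
#'   ids) and `treatment` (character vector, `"untreated"`/`"treated"` per
#'   column).
#' @export
simulate_organoid <- function(intersections, concordance_spec, mouse_truth,
                              orthologs, n_replicates = 3,
                              effect_log2fc = 0.5, n_background = 200,
                              nb_dispersion = 0.05,
                              base_log2_range = c(7, 10), seed = 1) {
  ids <- intersections$id
  bad <- setdiff(names(concordance_spec), ids)
  if (length(bad))
    .stop("concordance_spec references unknown intersection(s): ",
          paste(bad, collapse = ", "))
  if (!all(concordance_spec %in% c("concordant", "discordant", "null")))
    .stop("concordance classes must be concordant/discordant/null")
  orthologs <- orthologs_one_to_one(orthologs)
  .seed_rng(seed)

  # per-human-gene log2 treatment shift, averaging over set memberships
  shift_sum <- numeric(0); shift_n <- numeric(0)
  for (sid in names(concordance_spec)) {
    cls <- concordance_spec[[sid]]
    mult <- switch(cls, concordant = 1, discordant = -1, null = 0)
    delta <- mouse_truth[[sid]]
    if (is.null(delta)) .stop("mouse_truth missing for set ", sid)
    genes_m <- intersections$genes[[match(sid, ids)]]
    genes_h <- orthologs$gene_b[match(genes_m, orthologs$gene_a)]
    genes_h <- genes_h[!is.na(genes_h)]
    if (!length(genes_h)) {
      warning("intersection ", sid, " has no mapped orthologs; skipped")
      next
    }
    s <- mult * delta * effect_log2fc
    for (g in genes_h) {
      shift_sum[g] <- (if (g %in% names(shift_sum)) shift_sum[g] else 0) + s
      shift_n[g] <- (if (g %in% names(shift_n)) shift_n[g] else 0) + 1
    }
  }
  all_set_genes <- unique(unlist(intersections$genes[match(names(concordance_spec), ids)]))
  mapped <- orthologs$gene_b[match(all_set_genes, orthologs$gene_a)]
  mapped <- mapped[!is.na(mapped)]
  gene_ids <- unique(c(mapped, sprintf("HS_bg%04d", seq_len(n_background))))
  shift <- numeric(length(gene_ids)); names(shift) <- gene_ids
  got <- intersect(names(shift_sum), gene_ids)
  shift[got] <- shift_sum[got] / shift_n[got]

  n <- 2 * n_replicates
  treatment <- rep(c("untreated", "treated"), each = n_replicates)
  base <- runif(length(gene_ids), base_log2_range[1], base_log2_range[2])
  log2mu <- matrix(base, length(gene_ids), n)
  log2mu[, treatment == "treated"] <- log2mu[, treatment == "treated"] + shift
  counts <- matrix(rnbinom(length(log2mu), mu = 2^log2mu, size = 1 / nb_dispersion),
                   nrow(log2mu), n,
                   dimnames = list(gene_ids,
                                   paste0(rep(c("U", "T"), each = n_replicates),
                                          seq_len(n_replicates))))
  storage.mode(counts) <- "integer"
  list(counts = counts, treatment = treatment)
}
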