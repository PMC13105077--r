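# Synthetic cohort and count generation with known ground truth.
#
# The generator emulates the study design the pipeline was written for: a
# two-age, two-sex, five-genotype mouse cohort with sequencing-batch
# structure, negative-binomial gene counts, and haplotype effects injected at
# the gene-set level on the log2 scale under a dominant allele coding.

#' Default sex-marker gene ids
#'
#' The female marker is an Xist-like X-inactivation transcript; the two male
#' markers are Y-linked (Eif2s3y- and Ddx3y-like). Ids are the Ensembl ids
#' used for sex validation in mouse bulk RNA-seq.
#' @export
sex_marker_spec <- function() {
  list(female = "ENSMUSG00000086503",
       male   = c("ENSMUSG00000069049", "ENSMUSG00000069045"))
}

#' Describe a synthetic cohort
#'
#' @param n_per_cell samples per (genotype, sex, age) cell: a single integer,
#'   or a data.frame with columns `genotype`, `sex`, `age_cohort`, `n` giving
#'   each cell its own size (cells absent from the table get 0 samples).
#' @param genotypes genotype labels, a subset of [kl_genotypes].
#' @param ages age-cohort labels, e.g. `c("4mo", "12mo")`.
#' @param sexes sex labels, a subset of `c("F", "M")`.
#' @param n_batches number of sequencing batches (>= 1).
#' @param seed integer seed stored with the design and used by downstream
#'   simulators as their default.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_cell = 5, genotypes = kl_genotypes,
                          ages = c("4mo", "12mo"), sexes = c("F", "M"),
                          n_batches = 2, seed = 1) {
  if (!length(genotypes) || !length(ages) || !length(sexes))
    .stop("invalid design: genotypes, ages and sexes must all be non-empty")
  haplotype_group(genotypes)  # validates labels
  if (!.is_count(n_batches)) .stop("invalid design: n_batches must be an integer >= 1")
  if (is.data.frame(n_per_cell)) {
    need <- c("genotype", "sex", "age_cohort", "n")
    if (!all(need %in% names(n_per_cell)))
      .stop("cell-size table needs columns: ", paste(need, collapse = ", "))
    if (any(n_per_cell$n < 1)) .stop("invalid design: all cell counts must be >= 1")
  } else if (!.is_count(n_per_cell)) {
    .stop("invalid design: n_per_cell must be an integer >= 1 or a cell table")
  }
  structure(list(n_per_cell = n_per_cell, genotypes = genotypes, ages = ages,
                 sexes = sexes, n_batches = n_batches, seed = seed),
            class = "cohort_design")
}

#' Generate the per-sample metadata table for a design
#'
#' One row per sample with genotype, derived haplotype group, sex, age cohort
#' and batch. Batches are assigned round-robin (continuing across cells so
#' batches stay balanced overall); the whole table is a deterministic
#' function of the design.
#'
#' @param design a [cohort_design()].
#' @return data.frame with columns `sample_id`, `genotype`,
#'   `haplotype_group`, `sex`, `age_cohort`, `batch`.
#' @export
simulate_cohort <- function(design) {
  if (!inherits(design, "cohort_design")) .stop("design must be a cohort_design")
  cells <- expand.grid(genotype = design$genotypes, sex = design$sexes,
                       age_cohort = design$ages, KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  if (is.data.frame(design$n_per_cell)) {
    key <- function(d) paste(d$genotype, d$sex, d$age_cohort)
    n <- design$n_per_cell$n[match(key(cells),
      paste(design$n_per_cell$genotype, design$n_per_cell$sex,
            design$n_per_cell$age_cohort))]
    n[is.na(n)] <- 0L
  } else {
    n <- rep(design$n_per_cell, nrow(cells))
  }
  idx <- rep(seq_len(nrow(cells)), n)
  out <- cells[idx, , drop = FALSE]
  total <- nrow(out)
  if (!total) .stop("design produced zero samples")
  out$sample_id <- sprintf("S%03d", seq_len(total))
  out$haplotype_group <- haplotype_group(out$genotype)
  out$batch <- sprintf("B%d", ((seq_len(total) - 1L) %% design$n_batches) + 1L)
  rownames(out) <- NULL
  out[, c("sample_id", "genotype", "haplotype_group", "sex", "age_cohort", "batch")]
}

#' Declare a planted set-level haplotype effect
#'
#' @param set_id id of a gene set known to the generator.
#' @param delta signed effect in units of the within-group SD of the set-mean
#'   expression; positive means higher expression in VS carriers than FC
#'   carriers.
#' @param age_restricted if TRUE the effect is present only in the oldest
#'   cohort (emulating effects that appear at 12 months but not 4 months).
#' @param coding `"dominant"` (het and hom carriers get the full effect, the
#'   generator default) or `"additive"` (heterozygotes get half).
#' @export
effect_truth <- function(set_id, delta, age_restricted = FALSE,
                         coding = c("dominant", "additive")) {
  coding <- match.arg(coding)
  stopifnot(is.character(set_id), length(set_id) == 1L,
            is.numeric(delta), length(delta) == 1L, is.finite(delta))
  structure(list(set_id = set_id, delta = delta,
                 age_restricted = isTRUE(age_restricted), coding = coding),
            class = "effect_truth")
}

#' Predicted within-group SD of a set's mean log2 expression
#'
#' Closed form used by the generator to convert a standardized effect `delta`
#' into a log2-scale shift: for NB counts with mean `mu` and dispersion
#' `phi`, `var(log2 X) ~ (1/mu + phi) / ln(2)^2` (delta method), and the mean
#' of `m` independent genes divides the summed variance by `m^2`.
#'
#' @param base_log2_mean per-gene baseline log2 mean counts for the set.
#' @param dispersion NB dispersion `phi` (`var = mu + phi mu^2`).
#' @export
predicted_set_mean_sd <- function(base_log2_mean, dispersion) {
  mu <- 2^base_log2_mean
  sqrt(sum(1 / mu + dispersion)) / (log(2) * length(mu))
}

#' Simulate a gene-level count matrix with planted set-level effects
#'
#' Counts are negative-binomial with a single dispersion. Per-gene log2 means
#' are a baseline plus additive batch offsets (drawn once per batch), optional
#' per-gene sex and age offsets, and planted haplotype effects: each gene of
#' an affected set is shifted by `+delta * sigma_set / 2` in VS carriers and
#' `-delta * sigma_set / 2` in FC carriers (`sigma_set` from
#' [predicted_set_mean_sd()]), so the standardized VS - FC set-mean
#' difference equals `delta`. Under dominant coding heterozygous and
#' homozygous carriers get the full shift; under additive coding
#' heterozygotes get half. Age-restricted effects apply only to the oldest
#' cohort. Three deterministic sex-marker genes (see [sex_marker_spec()]) are
#' appended unless disabled.
#'
#' @param samples cohort table from [simulate_cohort()].
#' @param gene_sets optional [gene_set_collection()] the truth refers to.
#' @param truth list of [effect_truth()] objects (empty = global null).
#' @param n_genes total genes excluding markers; must cover the set union.
#' @param nb_dispersion NB dispersion (> 0).
#' @param batch_sd SD of log2-scale batch offsets.
#' @param base_log2_range range of per-gene baseline log2 means.
#' @param sex_log2fc,age_log2fc optional named numeric vectors (gene id ->
#'   log2 offset) applied to male / oldest-cohort samples.
#' @param include_sex_markers append the deterministic marker genes.
#' @param seed integer seed.
#' @return integer matrix (genes x samples) with attributes
#'   `truth_log2fc` (per planted set: the per-gene log2 shift between VS and
#'   FC carriers), `sigma_set` (predicted set-mean SD per planted set) and
#'   `batch_offsets`.
#' @export
simulate_counts <- function(samples, gene_sets = NULL, truth = list(),
                            n_genes = 1000, nb_dispersion = 0.05,
                            batch_sd = 0.15, base_log2_range = c(7, 10),
                            sex_log2fc = NULL, age_log2fc = NULL,
                            include_sex_markers = TRUE, seed = 1) {
  samples <- .check_samples(samples)
  if (nb_dispersion <= 0) .stop("nb_dispersion must be > 0")
  if (inherits(truth, "effect_truth")) truth <- list(truth)
  set_ids <- vapply(truth, `[[`, "", "set_id")
  if (length(truth)) {
    if (is.null(gene_sets)) .stop("truth supplied without gene_sets")
    bad <- setdiff(set_ids, names(gene_sets$sets))
    if (length(bad)) .stop("truth references unknown set(s): ",
                           paste(bad, collapse = ", "))
  }
  set_union <- if (is.null(gene_sets)) character(0) else
    unique(unlist(gene_sets$sets, use.names = FALSE))
  if (n_genes < length(set_union))
    .stop("n_genes must be at least the size of the gene-set union")
  filler <- setdiff(sprintf("gene%05d", seq_len(n_genes + length(set_union))),
                    set_union)
  gene_ids <- c(set_union, filler[seq_len(n_genes - length(set_union))])

  .seed_rng(seed)
  n <- nrow(samples)
  base <- runif(n_genes, base_log2_range[1], base_log2_range[2])
  names(base) <- gene_ids
  batches <- sort(unique(samples$batch))
  b_off <- rnorm(length(batches), 0, batch_sd)
  names(b_off) <- batches

  log2mu <- matrix(base, n_genes, n, dimnames = list(gene_ids, samples$sample_id))
  log2mu <- log2mu + rep(b_off[samples$batch], each = n_genes)
  if (!is.null(sex_log2fc)) {
    g <- intersect(names(sex_log2fc), gene_ids)
    log2mu[g, samples$sex == "M"] <- log2mu[g, samples$sex == "M"] + sex_log2fc[g]
  }
  is_old <- .age_rank(samples$age_cohort) == max(.age_rank(samples$age_cohort))
  if (!is.null(age_log2fc)) {
    g <- intersect(names(age_log2fc), gene_ids)
    log2mu[g, is_old] <- log2mu[g, is_old] + age_log2fc[g]
  }

  truth_fc <- numeric(0); sigma_rec <- numeric(0)
  hap <- as.character(samples$haplotype_group)
  het <- samples$genotype %in% c("WT/FC", "WT/VS")
  for (t in truth) {
    genes <- gene_sets$sets[[t$set_id]]
    sigma <- predicted_set_mean_sd(base[genes], nb_dispersion)
    shift <- t$delta * sigma / 2                    # applied +/- to VS/FC
    dose <- ifelse(hap == "VS", 1, ifelse(hap == "FC", -1, 0))
    if (t$coding == "additive") dose <- dose * ifelse(het, 0.5, 1)
    if (t$age_restricted) dose[!is_old] <- 0
    log2mu[genes, ] <- log2mu[genes, ] + outer(rep(2 * shift, length(genes)), dose) / 2
    truth_fc[t$set_id] <- 2 * shift                 # full VS - FC log2 shift
    sigma_rec[t$set_id] <- sigma
  }

  counts <- matrix(rnbinom(n_genes * n, mu = 2^log2mu, size = 1 / nb_dispersion),
                   n_genes, n, dimnames = dimnames(log2mu))
  if (include_sex_markers) {
    mk <- sex_marker_spec()
    male <- samples$sex == "M"
    markers <- rbind(ifelse(male, 0L, 1000L),
                     ifelse(male, 800L, 0L),
                     ifelse(male, 600L, 0L))
    rownames(markers) <- c(mk$female, mk$male)
    colnames(markers) <- colnames(counts)
    counts <- rbind(counts, markers)
  }
  storage.mode(counts) <- "integer"
  structure(counts, truth_log2fc = truth_fc, sigma_set = sigma_rec,
            batch_offsets = b_off)
}

#' Simulate a hierarchical gene-set collection and pathway collection
#'
#' Builds a Biodomain-style collection (domains with child subdomains, the
#' domain set being the union of its subdomains) and a flat KEGG-style
#' pathway collection over a shared gene universe, for use as fixtures.
#'
#' @param gene_ids gene universe to draw from.
#' @param n_domains,subdomains_per_domain hierarchy shape (defaults emulate a
#'   19-domain / 80-subdomain annotation at reduced scale).
#' @param subdomain_size genes per subdomain.
#' @param n_pathways,pathway_size flat pathway collection shape.
#' @param overlap fraction of each pathway drawn from the genes of
#'   `domains_per_pathway` randomly chosen domains, concentrating overlap so
#'   pathway-by-domain intersections clear a size filter the way curated
#'   annotations do.
#' @param domains_per_pathway domains each pathway concentrates on.
#' @param seed integer seed.
#' @return list with elements `biodomains` and `kegg`, both
#'   [gene_set_collection()]s.
#' @export
simulate_gene_sets <- function(gene_ids, n_domains = 6,
                               subdomains_per_domain = 4,
                               subdomain_size = 20, n_pathways = 15,
                               pathway_size = 40, overlap = 0.7,
                               domains_per_pathway = 2, seed = 1) {
  .seed_rng(seed)
  sets <- list(); hier <- character(0)
  for (d in seq_len(n_domains)) {
    dom <- sprintf("Domain%02d", d)
    dom_genes <- character(0)
    for (s in seq_len(subdomains_per_domain)) {
      sub <- sprintf("%s.sub%02d", dom, s)
      g <- sample(gene_ids, subdomain_size)
      sets[[sub]] <- sort(g)
      hier[sub] <- dom
      dom_genes <- union(dom_genes, g)
    }
    sets[[dom]] <- sort(dom_genes)
  }
  bio <- gene_set_collection(sets, hierarchy = hier, source = "synthetic-biodomains")
  kegg_sets <- list()
  dom_names <- sprintf("Domain%02d", seq_len(n_domains))
  for (p in seq_len(n_pathways)) {
    focus <- sample(dom_names, min(domains_per_pathway, n_domains))
    n_in <- round(pathway_size * overlap / length(focus))
    g <- unlist(lapply(focus, function(d)
      sample(sets[[d]], min(n_in, length(sets[[d]])))))
    rest <- setdiff(gene_ids, g)
    g <- c(g, sample(rest, max(0, pathway_size - length(g))))
    kegg_sets[[sprintf("map%05d", p)]] <- sort(unique(g))
  }
  list(biodomains = bio,
       kegg = gene_set_collection(kegg_sets, source = "synthetic-kegg"))
}

#' Simulate a one-to-one ortholog map
#'
#' @param gene_ids species-A (mouse-style) gene ids.
#' @param n_many_to_many extra ambiguous rows appended to exercise the strict
#'   one-to-one filter downstream.
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
simulate_orthologs <- function(gene_ids, n_many_to_many = 0, seed = 1) {
  .seed_rng(seed)
  out <- data.frame(gene_a = gene_ids,
                    gene_b = paste0("HS_", gene_ids),
                    stringsAsFactors = FALSE)
  if (n_many_to_many > 0) {
    dup <- sample(gene_ids, n_many_to_many, replace = TRUE)
    out <- rbind(out, data.frame(gene_a = dup,
                                 gene_b = paste0("HS_ALT_", dup)))
  }
  out
}
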