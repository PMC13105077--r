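# End-to-end orchestration of the synthetic study: simulate -> normalize ->
# per-gene DEG -> gene sets -> trend/screen -> exon usage -> cross-system
# comparison, with a run manifest recording parameters, outputs and warnings.

#' Default pipeline configuration
#'
#' Thresholds default to the analysis' stated values: gene-level and
#' subdomain FDR 0.05, intersection FDR 0.001, minimum intersection size 10,
#' DTU adjusted-p 0.05, organoid transcript total-count filter 10.
#'
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory.
#' @return named list, the `config` argument of [run_pipeline()].
#' @export
default_config <- function(seed = 1, out_dir = tempfile("haplodomain_run")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = list(simulate = TRUE, normalize = TRUE, deg = TRUE, sets = TRUE,
                  assoc = TRUE, dtu = TRUE, compare = TRUE),
    deg_fdr = 0.05,
    subdomain_fdr = 0.05,
    intersection_fdr = 0.001,
    min_intersection = 10,
    dtu_fdr = 0.05,
    organoid_min_total = 10,
    simulate = list(n_per_cell = 5, n_batches = 2, n_genes = 3000,
                    nb_dispersion = 0.05, batch_sd = 0.15,
                    n_planted = 8, planted_delta = 2,
                    dtu_genes = 20, dtu_planted = 4, dtu_shift = 0.25,
                    exon_depth = 500, dm_precision = 50)
  )
}

.validate_config <- function(config) {
  for (th in c("deg_fdr", "subdomain_fdr", "intersection_fdr", "dtu_fdr")) {
    v <- config[[th]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      .stop("config threshold '", th, "' must be in (0, 1]")
  }
  if (config$min_intersection < 2)
    .stop("min_intersection must be >= 2")
  config
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order, writes every stage's
#' table under `config$out_dir`, and returns a manifest with parameters,
#' output checksums and aggregated warnings. Identical config (including
#' seed) reproduces identical outputs.
#'
#' @param config list as produced by [default_config()], or a path to a YAML
#'   file with the same structure (missing entries take the defaults).
#' @return invisibly, the run manifest (also written as `manifest.yaml`).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config(seed = config$seed %||% 1)
  config <- utils::modifyList(base, config)
  config <- .validate_config(config)
  st <- config$stages
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings <- character(0)
  note <- function(path) outputs[[basename(path)]] <<- unname(tools::md5sum(path))
  run_stage <- function(code) {
    withCallingHandlers(code, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  need <- function(obj, stage, upstream) {
    if (is.null(obj)) .stop("stage '", stage, "' needs output of disabled stage '",
                            upstream, "'")
    obj
  }
  sp <- config$simulate
  samples <- counts <- expr <- sets <- inters <- truth <- NULL
  fits <- screened <- NULL

  if (isTRUE(st$simulate)) run_stage({
    design <- cohort_design(n_per_cell = sp$n_per_cell,
                            n_batches = sp$n_batches, seed = config$seed)
    samples <- simulate_cohort(design)
    gene_ids <- sprintf("gene%05d", seq_len(sp$n_genes))
    gs <- simulate_gene_sets(gene_ids, seed = config$seed)
    sets <- gs
    inters <- build_intersections(gs$kegg, gs$biodomains,
                                  min_size = config$min_intersection)
    planted_ids <- inters$id[seq_len(min(sp$n_planted, nrow(inters)))]
    sgn <- rep_len(c(1, -1), length(planted_ids))
    truth <- Map(function(id, s) effect_truth(id, s * sp$planted_delta,
                                              age_restricted = TRUE),
                 planted_ids, sgn)
    inter_coll <- gene_set_collection(stats::setNames(inters$genes, inters$id),
                                      source = "intersections")
    counts <- simulate_counts(samples, inter_coll, truth,
                              n_genes = sp$n_genes,
                              nb_dispersion = sp$nb_dispersion,
                              batch_sd = sp$batch_sd, seed = config$seed)
    write_samples(samples, file.path(config$out_dir, "samples.tsv"))
    write_counts(counts, file.path(config$out_dir, "counts.tsv"))
    write_gmt(gs$biodomains, file.path(config$out_dir, "biodomains.gmt"))
    write_gmt(gs$kegg, file.path(config$out_dir, "kegg.gmt"))
    note(file.path(config$out_dir, "samples.tsv"))
    note(file.path(config$out_dir, "counts.tsv"))
  })

  if (isTRUE(st$normalize)) run_stage({
    counts <- need(counts, "normalize", "simulate")
    expr <- vst(counts)
    expr <- residualize(expr, samples, "batch")
    path <- file.path(config$out_dir, "expression.tsv")
    write_counts(expr, path,
                 header = sprintf("normalized; residualized=%s; pseudocount=%g; factors=%s",
                                  paste(attr(expr, "residualized"), collapse = ","),
                                  attr(expr, "provenance")$pseudocount,
                                  attr(expr, "provenance")$factor_method))
    note(path)
  })

  deg_summary <- NULL
  if (isTRUE(st$deg)) run_stage({
    expr <- need(expr, "deg", "normalize")
    ts <- fit_factorial(expr, samples)
    path <- file.path(config$out_dir, "term_stats.tsv")
    utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    deg_summary <- count_deg(ts, fdr = config$deg_fdr)
    per_cohort <- lapply(split(samples$sample_id, samples$age_cohort), function(ids) {
      count_deg(fit_factorial(expr[, ids, drop = FALSE],
                              samples[samples$sample_id %in% ids, ]),
                fdr = config$deg_fdr)
    })
    summ <- c(list(all = deg_summary), per_cohort)
    path2 <- file.path(config$out_dir, "deg_counts.tsv")
    tab <- do.call(rbind, lapply(names(summ), function(nm)
      data.frame(cohort = nm, term = names(summ[[nm]]),
                 n_deg = as.integer(summ[[nm]]))))
    utils::write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path2)
  })

  if (isTRUE(st$assoc)) run_stage({
    expr <- need(expr, "assoc", "normalize")
    inters <- need(inters, "assoc", "simulate")
    expr_sex <- residualize(expr, samples, "sex")
    old <- samples$age_cohort[.age_rank(samples$age_cohort) ==
                                max(.age_rank(samples$age_cohort))][1]
    ids <- samples$sample_id[samples$age_cohort == old]
    sm <- set_means_matrix(expr_sex[, ids, drop = FALSE],
                           stats::setNames(inters$genes, inters$id))
    fits <- fit_trend_sets(sm, samples[samples$sample_id %in% ids, ])
    screened <- screen_sets(fits, fdr = config$intersection_fdr)
    path <- file.path(config$out_dir, "intersection_trend.tsv")
    utils::write.table(fits, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
    if (nrow(screened)) {
      bm <- biadjacency(screened)
      path2 <- file.path(config$out_dir, "biadjacency.tsv")
      write_biadjacency(bm, path2)
      note(path2)
    }
  })

  dtu_res <- NULL
  if (isTRUE(st$dtu)) run_stage({
    samples <- need(samples, "dtu", "simulate")
    dt <- lapply(seq_len(sp$dtu_planted), function(i)
      dtu_truth(sprintf("dgene%04d", i), 1, sp$dtu_shift,
                precision = sp$dm_precision))
    exons <- simulate_exon_counts(samples, dt, n_genes = sp$dtu_genes,
                                  depth = sp$exon_depth,
                                  precision = sp$dm_precision,
                                  seed = config$seed + 1)
    exons_f <- filter_features(exons)
    dtu_res <- dtu_test(exons_f, samples)
    path <- file.path(config$out_dir, "dtu_results.tsv")
    utils::write.table(dtu_res, path, sep = "\t", quote = FALSE, row.names = FALSE)
    note(path)
  })

  comparison <- NULL
  if (isTRUE(st$compare)) run_stage({
    fits <- need(fits, "compare", "assoc")
    inters <- need(inters, "compare", "simulate")
    orth <- simulate_orthologs(unique(unlist(inters$genes)),
                               seed = config$seed)
    spec <- stats::setNames(rep("concordant", length(truth)),
                            vapply(truth, `[[`, "", "set_id"))
    deltas <- stats::setNames(vapply(truth, `[[`, 0, "delta"), names(spec))
    org <- simulate_organoid(inters[inters$id %in% names(spec), ], spec,
                             deltas, orth, seed = config$seed + 2)
    oc <- filter_transcripts(org$counts, min_total = config$organoid_min_total)
    oexpr <- vst(oc)
    betas <- treatment_effects(oexpr, org$treatment,
                               inters[inters$id %in% names(spec), ], orth)
    comparison <- compare_effects(fits, betas)
    path <- file.path(config$out_dir, "cross_system.tsv")
    utils::write.table(comparison$comparison, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note(path)
  })

  manifest <- list(
    parameters = config[setdiff(names(config), "stages")],
    stages_run = names(st)[vapply(st, isTRUE, TRUE)],
    outputs = as.list(outputs),
    n_significant_intersections = if (!is.null(screened)) nrow(screened),
    deg_counts = if (!is.null(deg_summary)) as.list(deg_summary),
    dtu_significant = if (!is.null(dtu_res))
      sum(dtu_res$p_adj <= config$dtu_fdr, na.rm = TRUE),
    cross_system_rho = if (!is.null(comparison)) comparison$rho,
    warnings = warnings)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
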