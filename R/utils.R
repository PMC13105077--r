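#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop <- function(...) stop(..., call. = FALSE)

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)

# Set RNG state from an integer seed without touching the caller's stream
# beyond this call (simulators are documented as seeding the global RNG).
.seed_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  invisible(NULL)
}

#' Map engineered genotypes to haplotype carrier groups
#'
#' Carriers of each humanized allele are grouped dominantly: heterozygous and
#' homozygous FC-allele animals form the FC group, VS carriers the VS group,
#' and wild-type animals the WT group.
#'
#' @param genotype character vector over `"WT/WT"`, `"WT/FC"`, `"FC/FC"`,
#'   `"WT/VS"`, `"VS/VS"`.
#' @return factor with levels `FC`, `WT`, `VS` (the order used by the
#'   ordered-haplotype trend model).
#' @export
haplotype_group <- function(genotype) {
  map <- c("WT/WT" = "WT", "WT/FC" = "FC", "FC/FC" = "FC",
           "WT/VS" = "VS", "VS/VS" = "VS")
  bad <- setdiff(unique(as.character(genotype)), names(map))
  if (length(bad))
    .stop("unknown genotype(s): ", paste(bad, collapse = ", "))
  factor(unname(map[as.character(genotype)]), levels = c("FC", "WT", "VS"))
}

#' @rdname haplotype_group
#' @format `kl_genotypes` is the character vector of valid genotype labels.
#' @export
kl_genotypes <- c("WT/WT", "WT/FC", "FC/FC", "WT/VS", "VS/VS")

# Validate a sample metadata table and coerce its columns.
.check_samples <- function(samples) {
  need <- c("sample_id", "genotype", "sex", "age_cohort", "batch")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    .stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    .stop("duplicate sample_id in sample table")
  hg <- haplotype_group(samples$genotype)
  if (!is.null(samples$haplotype_group) &&
      !all(as.character(samples$haplotype_group) == as.character(hg)))
    .stop("haplotype_group column inconsistent with genotype under the dominant grouping rule")
  samples$haplotype_group <- hg
  samples
}

# Align count/expression matrix columns to a sample table by id (never by
# order); mismatch is a hard error.
.align_samples <- function(mat, samples) {
  samples <- .check_samples(samples)
  if (is.null(colnames(mat)))
    .stop("matrix has no column (sample) names; cannot match to metadata")
  if (!setequal(colnames(mat), samples$sample_id))
    .stop("matrix samples and metadata sample_ids do not match")
  samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
}

# Ranks age labels like "4mo", "12mo" by leading number; used to decide which
# cohort is "old" for age-restricted effects.
.age_rank <- function(age) {
  num <- suppressWarnings(as.numeric(sub("^([0-9]+\\.?[0-9]*).*$", "\\1", age)))
  if (anyNA(num)) as.numeric(factor(age)) else num
}
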