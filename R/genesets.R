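# Gene-set collections: GMT parsing, a domain -> subdomain hierarchy,
# per-sample set-mean expression, and pathway-by-domain intersection sets.

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> gene ids);
#'   duplicate genes within a set are removed.
#' @param hierarchy optional named character vector mapping subdomain set
#'   names to their parent domain; every parent must itself be a set in the
#'   collection.
#' @param source free-text label of where the collection came from.
#' @export
gene_set_collection <- function(sets, hierarchy = NULL, source = "") {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == ""))
    .stop("sets must be a non-empty named list")
  if (anyDuplicated(names(sets))) .stop("duplicate set names")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (!is.null(hierarchy)) {
    unknown_child <- setdiff(names(hierarchy), names(sets))
    if (length(unknown_child))
      .stop("hierarchy names sets not in the collection: ",
            paste(unknown_child, collapse = ", "))
    unknown_parent <- setdiff(unique(hierarchy), names(sets))
    if (length(unknown_parent))
      .stop("hierarchy parent(s) not in the collection's domain list: ",
            paste(unknown_parent, collapse = ", "))
  }
  structure(list(sets = sets, hierarchy = hierarchy, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets",
      if (!is.null(x$hierarchy)) sprintf("(%d with parents)", length(x$hierarchy)),
      if (nzchar(x$source)) paste0("[", x$source, "]"), "\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated `name`,
#' `description`, members. Duplicate members are dropped with a warning;
#' sets left empty are dropped with a warning. A description of the form
#' `parent=<domain>` records the set's parent domain in the collection
#' hierarchy (the convention [write_gmt()] emits).
#'
#' @param path GMT file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); hier <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      .stop("malformed GMT line ", i, ": fewer than 3 fields")
    name <- fields[1]; desc <- fields[2]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate members in set '", name, "' deduplicated")
      genes <- unique(genes)
    }
    if (!length(genes)) {
      warning("empty set '", name, "' dropped")
      next
    }
    sets[[name]] <- genes
    if (grepl("^parent=", desc)) hier[name] <- sub("^parent=", "", desc)
  }
  if (!length(sets)) .stop("no non-empty sets in ", path)
  hier <- hier[names(hier) %in% names(sets)]
  gene_set_collection(sets, hierarchy = if (length(hier)) hier else NULL,
                      source = path)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    desc <- if (!is.null(collection$hierarchy) && nm %in% names(collection$hierarchy))
      paste0("parent=", collection$hierarchy[[nm]]) else "na"
    paste(c(nm, desc, collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Per-sample mean expression of a gene set
#'
#' Unweighted arithmetic mean over the set's genes present in the matrix;
#' genes absent from the matrix are dropped (their number is reported in the
#' `n_missing` attribute), never imputed.
#'
#' @param expr expression matrix, genes x samples.
#' @param genes character vector of gene ids, or a set name present in
#'   `collection`.
#' @param collection optional [gene_set_collection()] to resolve a set name.
#' @param set_name label used in error messages.
#' @return numeric vector of per-sample means with attribute `n_missing`.
#' @export
set_mean_expression <- function(expr, genes, collection = NULL,
                                set_name = NULL) {
  if (!is.null(collection)) {
    set_name <- set_name %||% genes
    genes <- collection$sets[[genes]]
    if (is.null(genes)) .stop("set '", set_name, "' not in collection")
  }
  present <- intersect(genes, rownames(expr))
  if (!length(present))
    .stop("no genes of set '", set_name %||% "<anonymous>",
          "' are present in the expression matrix")
  means <- colMeans(expr[present, , drop = FALSE])
  attr(means, "n_missing") <- length(genes) - length(present)
  means
}

#' Set-mean expression for many sets at once
#'
#' @param expr expression matrix.
#' @param sets named list of gene-id vectors (or a [gene_set_collection()]).
#' @param min_present sets with fewer expressed genes are dropped with a
#'   warning.
#' @return sets x samples matrix of means.
#' @export
set_means_matrix <- function(expr, sets, min_present = 1) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  keep <- vapply(sets, function(g) sum(g %in% rownames(expr)) >= min_present,
                 TRUE)
  if (!all(keep))
    warning(sum(!keep), " set(s) dropped: fewer than ", min_present,
            " genes present in the expression matrix")
  sets <- sets[keep]
  out <- t(vapply(names(sets), function(nm)
    as.numeric(set_mean_expression(expr, sets[[nm]], set_name = nm)),
    numeric(ncol(expr))))
  colnames(out) <- colnames(expr)
  out
}

#' Intersect pathway and domain collections
#'
#' All pathway-by-domain pairs are evaluated; intersections with at least
#' `min_size` genes (annotated membership, not expression-filtered) are
#' retained, ordered by pathway then domain name.
#'
#' @param kegg pathway [gene_set_collection()].
#' @param biodomains domain [gene_set_collection()] (subdomains allowed; all
#'   sets are used as supplied).
#' @param min_size minimum intersection size (default 10).
#' @return data.frame of class `intersection_sets` with columns `id`
#'   (`"<pathway> :: <domain>"`), `pathway`, `domain`, `size` and a `genes`
#'   list-column (sorted unique ids).
#' @export
build_intersections <- function(kegg, biodomains, min_size = 10) {
  if (!length(kegg$sets) || !length(biodomains$sets))
    .stop("both collections must be non-empty")
  p_names <- sort(names(kegg$sets))
  d_names <- sort(names(biodomains$sets))
  rows <- list()
  for (p in p_names) {
    for (d in d_names) {
      g <- sort(intersect(kegg$sets[[p]], biodomains$sets[[d]]))
      if (length(g) >= min_size)
        rows[[length(rows) + 1L]] <- list(p = p, d = d, g = g)
    }
  }
  out <- data.frame(
    id = vapply(rows, function(r) paste(r$p, r$d, sep = " :: "), ""),
    pathway = vapply(rows, `[[`, "", "p"),
    domain = vapply(rows, `[[`, "", "d"),
    size = vapply(rows, function(r) length(r$g), 0L),
    stringsAsFactors = FALSE)
  out$genes <- lapply(rows, `[[`, "g")
  attr(out, "n_pairs_evaluated") <- length(p_names) * length(d_names)
  class(out) <- c("intersection_sets", "data.frame")
  out
}

#' Write an intersection catalog as TSV
#'
#' @param intersections table from [build_intersections()].
#' @param path output path; gene lists are semicolon-joined.
#' @export
write_intersections <- function(intersections, path) {
  df <- data.frame(pathway = intersections$pathway,
                   domain = intersections$domain,
                   size = intersections$size,
                   genes = vapply(intersections$genes, paste, "",
                                  collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
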