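#' Gene-set collections
#'
#' A `gene_set_collection` is a lightweight container for named gene sets
#' (immune cell signatures, stromal/immune signatures, pathway sets): an
#' ordered list of unique-gene character vectors plus a one-line description
#' per set. Collections are read from and written to GMT, the tab-separated
#' format used throughout the GSEA ecosystem.
#'
#' @param genes Named list of character vectors (one per set).
#' @param descriptions Character vector of per-set descriptions, recycled to
#'   a single empty string if omitted.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(genes, descriptions = NULL) {
  if (!is.list(genes) || is.null(names(genes)) || any(names(genes) == ""))
    stop("'genes' must be a named list of character vectors")
  if (anyDuplicated(names(genes)))
    stop("duplicate set names: ",
         paste(unique(names(genes)[duplicated(names(genes))]), collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(genes))
  descriptions <- rep_len(as.character(descriptions), length(genes))
  names(descriptions) <- names(genes)
  genes <- lapply(genes, function(g) {
    g <- as.character(g)
    g <- g[!is.na(g) & nzchar(g)]
    unique(g)
  })
  if (any(lengths(genes) == 0L))
    stop("empty gene set(s) after construction: ",
         paste(names(genes)[lengths(genes) == 0L], collapse = ", "))
  if (any(vapply(genes, function(g) any(grepl("\t", g, fixed = TRUE)), logical(1))))
    stop("gene ids must not contain tab characters")
  structure(list(genes = genes, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection with %d set(s)\n", length(x$genes)))
  n <- min(length(x$genes), 6L)
  for (i in seq_len(n))
    cat(sprintf("  %s (%d genes)\n", names(x$genes)[i], length(x$genes[[i]])))
  if (length(x$genes) > n) cat(sprintf("  ... and %d more\n", length(x$genes) - n))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$genes)

#' @export
names.gene_set_collection <- function(x) names(x$genes)

#' Read a GMT file
#'
#' One set per line: set name, description, then member genes, all
#' tab-separated. Duplicate genes within a set are collapsed keeping the
#' first occurrence; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, "; returning empty collection")
    return(structure(list(genes = setNames(list(), character(0)),
                          descriptions = setNames(character(0), character(0))),
                     class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line(s) with fewer than 3 tab-separated fields: line ",
         paste(bad, collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s) in GMT: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  names(genes) <- nm
  gene_set_collection(genes, desc)
}

#' Write a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, p))` reproduces names,
#' descriptions and gene lists exactly.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$genes), function(i) {
    paste(c(names(collection$genes)[i], collection$descriptions[i],
            collection$genes[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a collection to the genes of an expression matrix
#'
#' Intersects each set with the measured genes and drops sets that fall
#' below `min_size`, with a warning. Dropped set names are attached as the
#' `"dropped"` attribute of the result. The operation is idempotent.
#'
#' @param collection A [gene_set_collection()].
#' @param gene_ids Character vector of measured gene ids.
#' @param min_size Minimum surviving set size; smaller sets are dropped.
#'   Defaults to 5: single-sample enrichment scores of tiny sets are
#'   dominated by rank noise.
#' @return A restricted [gene_set_collection()] with attribute `"dropped"`
#'   (character vector of dropped set names, possibly empty).
#' @export
restrict_to_matrix <- function(collection, gene_ids, min_size = 5L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(gene_ids) == 0L) stop("'gene_ids' must be non-empty")
  min_size <- as.integer(min_size)
  stopifnot(min_size >= 1L)
  kept <- lapply(collection$genes, function(g) g[g %in% gene_ids])
  drop <- lengths(kept) < min_size
  if (all(drop))
    stop("all gene sets dropped after restriction to the matrix ",
         "(min_size = ", min_size, "): nothing to score")
  if (any(drop))
    warning(sum(drop), " set(s) below min_size = ", min_size,
            " after restriction, dropped: ",
            paste(names(kept)[drop], collapse = ", "))
  out <- gene_set_collection(kept[!drop], collection$descriptions[!drop])
  attr(out, "dropped") <- names(kept)[drop]
  out
}
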