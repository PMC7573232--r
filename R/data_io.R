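# Readers and writers for the on-disk formats: count matrices, sample
# metadata, GMT gene sets, gene-id mapping tables, and the TSV/JSON outputs
# of the pipeline stages.

#' Validate a count matrix
#'
#' A count matrix is an integer-valued numeric matrix with unique, non-empty
#' gene ids as rownames and unique, non-empty sample ids as colnames. Gene
#' ids must also be unique after case normalization (uppercase, trimmed),
#' because downstream gene matching is case-insensitive.
#'
#' @param m matrix to validate.
#' @return `m`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_counts <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    stopf("count matrix must be a numeric matrix")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stopf("count matrix must have gene ids (rownames) and sample ids (colnames)")
  }
  if (ncol(m) == 0L) stopf("count matrix has an empty sample list")
  if (nrow(m) == 0L) stopf("count matrix has an empty gene list")
  if (any(!nzchar(rownames(m))) || any(!nzchar(colnames(m)))) {
    stopf("empty gene or sample identifier")
  }
  if (anyDuplicated(norm_gene_ids(rownames(m)))) {
    stopf("duplicate gene id: %s",
          rownames(m)[duplicated(norm_gene_ids(rownames(m)))][1L])
  }
  if (anyDuplicated(colnames(m))) stopf("duplicate sample id")
  if (anyNA(m)) stopf("missing values in counts")
  if (any(m < 0)) stopf("negative count")
  if (any(m != floor(m))) stopf("non-integer count")
  invisible(m)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' Expects a header row `gene_id<TAB>sample1<TAB>...` followed by one gene
#' per row with non-negative integer cells. Duplicate gene ids (after case
#' normalization) and ragged rows are errors.
#'
#' @param path path to a tab-separated count file.
#' @return numeric matrix (genes x samples) with integral values.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("count file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stopf("count file must have a header and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stopf("header must name at least one sample")
  samples <- header[-1L]
  width <- length(header)
  body <- fields[-1L]
  if (any(lengths(body) != width)) {
    stopf("ragged row: line %d has %d fields, expected %d",
          which(lengths(body) != width)[1L] + 1L,
          lengths(body)[lengths(body) != width][1L], width)
  }
  genes <- vapply(body, `[[`, character(1L), 1L)
  cells <- vapply(body, function(f) suppressWarnings(as.numeric(f[-1L])),
                  numeric(width - 1L))
  m <- if (is.matrix(cells)) t(cells) else matrix(cells, ncol = width - 1L)
  if (anyNA(m)) stopf("non-numeric count cell")
  if (any(m < 0)) stopf("negative count")
  dimnames(m) <- list(genes, samples)
  validate_counts(m)
  m
}

#' Write a count matrix to TSV
#'
#' Output is deterministic: the same matrix always produces byte-identical
#' files, and `read_counts()` on the result reproduces the matrix exactly.
#'
#' @param m validated count matrix.
#' @param path output path.
#' @export
write_counts <- function(m, path) {
  validate_counts(m)
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- paste(rownames(m),
                apply(m, 1L, function(r) {
                  paste(format(r, scientific = FALSE, trim = TRUE),
                        collapse = "\t")
                }),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# Normalized expression matrices carry fractional values; keep full double
# precision through the %.17g round-trip so seeded runs are byte-stable.
#' Write a normalized expression matrix to TSV
#' @param m numeric matrix (genes x samples).
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  header <- paste(c("gene_id", colnames(m)), collapse = "\t")
  body <- paste(rownames(m),
                apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a normalized expression matrix from TSV
#' @param path path to a tab-separated expression file (same layout as counts,
#'   real-valued cells).
#' @return numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(tab),
                                 dimnames = list(NULL, names(tab)[-1L]))
  rownames(m) <- tab[[1L]]
  if (anyNA(m)) stopf("non-numeric expression cell")
  m
}

#' Read a sample metadata table
#'
#' TSV with header columns `sample_id`, `condition`, and optionally
#' `subject_id` (for matched designs).
#'
#' @param path path to the metadata TSV.
#' @return data.frame with columns sample_id, condition, and subject_id
#'   when present.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("metadata file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (!all(c("sample_id", "condition") %in% names(tab))) {
    stopf("metadata must have columns sample_id and condition")
  }
  if (anyDuplicated(tab$sample_id)) stopf("duplicate sample_id in metadata")
  tab
}

#' Write a sample metadata table
#' @param meta data.frame with sample_id and condition columns.
#' @param path output path.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Cross-check that a metadata table and count matrix describe the same
# samples, returning metadata reordered to the matrix column order.
align_metadata <- function(m, meta) {
  if (!setequal(meta$sample_id, colnames(m))) {
    stopf("metadata samples do not match count matrix samples")
  }
  meta[match(colnames(m), meta$sample_id), , drop = FALSE]
}

#' Construct a gene set
#' @param name set name.
#' @param description free-text description.
#' @param genes character vector of member gene ids (deduplicated).
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, description = "", genes = character()) {
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stopf("gene set '%s' is empty", name)
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed with a warning.
#'
#' @param path path to the GMT file.
#' @return named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("empty GMT file")
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stopf("GMT line %d has %d fields; need name, description, >=1 gene",
            i, length(f))
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warnf("GMT set '%s': %d duplicate gene(s) collapsed",
            f[1L], sum(duplicated(genes)))
    }
    gene_set(f[1L], f[2L], genes)
  })
  names(sets) <- vapply(sets, `[[`, character(1L), "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of `gene_set` objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-id mapping table
#'
#' Two-column TSV (source id, target id), no header. Only pairs that are
#' one-to-one in both directions are retained; pairs with an ambiguous
#' source or target are dropped and the count is logged.
#'
#' @param path path to the mapping TSV.
#' @return data.frame with columns source_id, target_id.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stopf("mapping file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stopf("malformed mapping line %d: expected exactly 2 tab-separated fields",
          which(lengths(fields) != 2L)[1L])
  }
  map <- data.frame(source_id = vapply(fields, `[[`, character(1L), 1L),
                    target_id = vapply(fields, `[[`, character(1L), 2L),
                    stringsAsFactors = FALSE)
  keep <- !(map$source_id %in% map$source_id[duplicated(map$source_id)]) &
          !(map$target_id %in% map$target_id[duplicated(map$target_id)])
  if (any(!keep)) {
    nhs_log("read_mapping: dropped %d ambiguous (non one-to-one) pair(s)",
            sum(!keep))
  }
  map[keep, , drop = FALSE]
}

#' Write a gene-id mapping table
#' @param mapping data.frame with source_id and target_id columns.
#' @param path output path.
#' @export
write_mapping <- function(mapping, path) {
  writeLines(paste(mapping$source_id, mapping$target_id, sep = "\t"), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records inputs, parameters, seed and package version alongside every
#' pipeline output for provenance.
#'
#' @param path output JSON path.
#' @param ... named fields to record.
#' @export
write_run_manifest <- function(path, ...) {
  manifest <- c(list(package = "nohelpscore",
                     version = as.character(utils::packageVersion("nohelpscore"))),
                list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
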