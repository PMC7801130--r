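# Containers for UMI count data and gene sets, plus 10X MatrixMarket and GMT
# readers/writers. All internal gene addressing uses gene_ids; gene symbols
# may collide and are resolved explicitly via resolve_symbols().

#' Construct a CountMatrix
#'
#' Sparse genes x cells UMI count container with per-cell metadata. This is the
#' package's primary data model: rows are features addressed by unique
#' `gene_ids` (display symbols in `gene_names` may repeat), columns are cells
#' addressed by unique `barcodes`, and `cell_meta` carries one row per barcode
#' (typically `donor`, `condition`, `sample_id`).
#'
#' @param counts sparse or dense non-negative integer matrix, genes x cells.
#' @param gene_ids character vector of unique feature identifiers.
#' @param gene_names character vector of display symbols (defaults to
#'   `gene_ids`); may contain duplicates.
#' @param barcodes character vector of unique cell identifiers.
#' @param cell_meta data.frame with one row per cell, or NULL for an empty
#'   frame.
#' @return object of class `CountMatrix`.
#' @export
CountMatrix <- function(counts, gene_ids, gene_names = gene_ids, barcodes,
                        cell_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (length(counts@x) && any(counts@x < 0)) {
    stop_integrity("counts must be non-negative")
  }
  if (length(counts@x) && any(counts@x != round(counts@x))) {
    stop_integrity("counts must be integer UMI counts")
  }
  if (nrow(counts) != length(gene_ids)) {
    stop_integrity("gene_ids length (", length(gene_ids),
                   ") does not match row count (", nrow(counts), ")")
  }
  if (length(gene_names) != length(gene_ids)) {
    stop_integrity("gene_names and gene_ids lengths differ")
  }
  if (ncol(counts) != length(barcodes)) {
    stop_integrity("barcodes length (", length(barcodes),
                   ") does not match column count (", ncol(counts), ")")
  }
  if (anyDuplicated(gene_ids)) stop_integrity("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop_integrity("barcodes must be unique")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = barcodes)
  }
  if (nrow(cell_meta) != length(barcodes)) {
    stop_integrity("cell_meta must have exactly one row per barcode")
  }
  rownames(cell_meta) <- barcodes
  dimnames(counts) <- list(gene_ids, barcodes)
  structure(
    list(counts = counts,
         gene_ids = as.character(gene_ids),
         gene_names = as.character(gene_names),
         barcodes = as.character(barcodes),
         cell_meta = cell_meta),
    class = "CountMatrix")
}

#' @exportS3Method base::print
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells;",
      format(sum(x$counts), big.mark = ","), "total UMIs\n")
  if (ncol(x$cell_meta) > 0) {
    cat("cell_meta columns:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param m CountMatrix.
#' @param genes gene_ids (or logical/integer index) to keep; NULL keeps all.
#' @param cells barcodes (or logical/integer index) to keep; NULL keeps all.
#' @return CountMatrix restricted to the selection, metadata subset in step.
#' @export
subset_count_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "CountMatrix"))
  gi <- if (is.null(genes)) seq_along(m$gene_ids) else {
    if (is.character(genes)) match(genes, m$gene_ids) else seq_along(m$gene_ids)[genes]
  }
  if (anyNA(gi)) stop_integrity("unknown gene_ids in subset")
  ci <- if (is.null(cells)) seq_along(m$barcodes) else {
    if (is.character(cells)) match(cells, m$barcodes) else seq_along(m$barcodes)[cells]
  }
  if (anyNA(ci)) stop_integrity("unknown barcodes in subset")
  CountMatrix(m$counts[gi, ci, drop = FALSE],
              gene_ids = m$gene_ids[gi],
              gene_names = m$gene_names[gi],
              barcodes = m$barcodes[ci],
              cell_meta = m$cell_meta[ci, , drop = FALSE])
}

#' Resolve gene symbols to gene identifiers
#'
#' Signature and marker gene lists are symbol-based while all internal
#' addressing uses gene_ids. A symbol matching more than one gene_id is
#' ambiguous and raises an error rather than guessing.
#'
#' @param m CountMatrix or ExprMatrix.
#' @param symbols character vector of gene symbols.
#' @param missing_ok drop symbols absent from the matrix (default) instead of
#'   erroring.
#' @return character vector of gene_ids (order follows `symbols`).
#' @export
resolve_symbols <- function(m, symbols, missing_ok = TRUE) {
  tab <- split(m$gene_ids, m$gene_names)
  hit <- tab[symbols]
  nmatch <- lengths(hit)
  if (any(nmatch > 1)) {
    stop_integrity("ambiguous gene symbol(s): ",
                   paste(symbols[nmatch > 1], collapse = ", "))
  }
  if (!missing_ok && any(nmatch == 0)) {
    stop_integrity("symbol(s) not found: ",
                   paste(symbols[nmatch == 0], collapse = ", "))
  }
  unlist(hit, use.names = FALSE)
}

#' Construct an ExprMatrix
#'
#' Real-valued genes x cells expression container (ln-normalized values or
#' regression residuals) carrying the same axis labels as its source
#' CountMatrix plus an ordered log of the transforms applied.
#'
#' @param values numeric matrix (dense or sparse), genes x cells.
#' @param gene_ids,gene_names,barcodes,cell_meta axis labels and metadata, as
#'   in [CountMatrix()].
#' @param transform_log character vector naming transforms applied so far.
#' @return object of class `ExprMatrix`.
#' @export
ExprMatrix <- function(values, gene_ids, gene_names = gene_ids, barcodes,
                       cell_meta = NULL, transform_log = character()) {
  if (nrow(values) != length(gene_ids) || ncol(values) != length(barcodes)) {
    stop_integrity("values dimensions do not match axis labels")
  }
  if (anyDuplicated(gene_ids)) stop_integrity("gene_ids must be unique")
  if (anyDuplicated(barcodes)) stop_integrity("barcodes must be unique")
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = barcodes)
  rownames(cell_meta) <- barcodes
  dimnames(values) <- list(gene_ids, barcodes)
  structure(
    list(values = values,
         gene_ids = as.character(gene_ids),
         gene_names = as.character(gene_names),
         barcodes = as.character(barcodes),
         cell_meta = cell_meta,
         transform_log = transform_log),
    class = "ExprMatrix")
}

#' @exportS3Method base::print
print.ExprMatrix <- function(x, ...) {
  cat("ExprMatrix:", nrow(x$values), "genes x", ncol(x$values), "cells;",
      "transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ExprMatrix <- function(x) dim(x$values)

#' Construct a GeneSet
#'
#' @param name set name.
#' @param genes non-empty character vector of gene symbols; duplicates are
#'   removed with a warning.
#' @param description free-text description.
#' @return object of class `GeneSet`.
#' @export
GeneSet <- function(name, genes, description = "") {
  if (length(genes) == 0) stop_format("GeneSet '", name, "' has no genes")
  if (anyDuplicated(genes)) {
    warning("GeneSet '", name, "': duplicate symbols removed", call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = as.character(genes),
                 description = description),
            class = "GeneSet")
}

#' @exportS3Method base::print
print.GeneSet <- function(x, ...) {
  cat("GeneSet '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

# Locate a 10X file that may be gzipped and may use the v2 or v3 name.
find_10x_file <- function(directory, candidates) {
  for (nm in candidates) {
    for (p in file.path(directory, c(nm, paste0(nm, ".gz")))) {
      if (file.exists(p)) return(p)
    }
  }
  stop_format("missing 10X file in '", directory, "': expected one of ",
              paste(candidates, collapse = ", "), " (optionally gzipped)")
}

read_tsv_plain <- function(path, ...) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(data.frame(V1 = character(), V2 = character()))
  }
  read.delim(text = lines, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
             quote = "", comment.char = "", colClasses = "character", ...)
}

#' Read a 10X-style MatrixMarket directory
#'
#' Reads `matrix.mtx`, `barcodes.tsv` and either `features.tsv` (v3 dialect,
#' three columns: id, symbol, type) or `genes.tsv` (v2 dialect, two columns:
#' id, symbol), each optionally gzipped. The dialect is auto-detected from the
#' file name. An optional `cell_meta.tsv` (tab-separated, header, first column
#' barcode) is attached as per-cell metadata when present.
#'
#' @param directory path to the matrix directory.
#' @return [CountMatrix()] with genes in file order.
#' @export
read_10x_mtx <- function(directory) {
  if (!dir.exists(directory)) stop_format("no such directory: ", directory)
  mtx_path <- find_10x_file(directory, "matrix.mtx")
  feat_path <- tryCatch(find_10x_file(directory, "features.tsv"),
                        error = function(e) find_10x_file(directory, "genes.tsv"))
  bc_path <- find_10x_file(directory, "barcodes.tsv")

  counts <- Matrix::readMM(mtx_path)
  feats <- read_tsv_plain(feat_path)
  if (ncol(feats) < 2) {
    # v2 files written with a single column of ids are still usable
    feats$V2 <- feats$V1
  }
  barcodes <- read_tsv_plain(bc_path)[[1]]
  if (nrow(feats) != nrow(counts)) {
    stop_integrity("feature file has ", nrow(feats), " rows but matrix header ",
                   "declares ", nrow(counts), " rows")
  }
  if (length(barcodes) != ncol(counts)) {
    stop_integrity("barcode file has ", length(barcodes), " lines but matrix ",
                   "header declares ", ncol(counts), " columns")
  }
  meta <- NULL
  meta_path <- tryCatch(find_10x_file(directory, "cell_meta.tsv"),
                        error = function(e) NULL)
  if (!is.null(meta_path)) {
    mt <- read.delim(meta_path, sep = "\t", stringsAsFactors = FALSE)
    rownames(mt) <- mt[[1]]
    mt <- mt[barcodes, -1, drop = FALSE]
    meta <- mt
  }
  CountMatrix(counts, gene_ids = feats[[1]], gene_names = feats[[2]],
              barcodes = barcodes, cell_meta = meta)
}

#' Write a CountMatrix as a 10X-style directory
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate integer, 1-based),
#' `features.tsv` (v3 dialect: id, symbol, "Gene Expression"), `barcodes.tsv`,
#' and `cell_meta.tsv` when metadata is present. Round-trips exactly through
#' [read_10x_mtx()].
#'
#' @param m CountMatrix.
#' @param directory output directory (created if absent).
#' @return `directory`, invisibly.
#' @export
write_10x_mtx <- function(m, directory) {
  stopifnot(inherits(m, "CountMatrix"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop_format("cannot create directory: ", directory)
  tm <- as(m$counts, "TsparseMatrix")
  mtx <- file.path(directory, "matrix.mtx")
  con <- file(mtx, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(tm), ncol(tm), length(tm@x))), con)
  if (length(tm@x)) {
    writeLines(paste(tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
  }
  close(con)
  write.table(data.frame(id = m$gene_ids, name = m$gene_names,
                         type = rep("Gene Expression", length(m$gene_ids))),
              file.path(directory, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(m$barcodes, file.path(directory, "barcodes.tsv"))
  if (ncol(m$cell_meta) > 0) {
    meta <- cbind(barcode = m$barcodes, m$cell_meta)
    write.table(meta, file.path(directory, "cell_meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(directory)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then one gene symbol per
#' field. Duplicate symbols within a line are removed with a warning.
#'
#' @param path GMT file (optionally gzipped).
#' @return named list of [GeneSet()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_format("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_format("GMT line ", i, " has ", length(f),
                  " fields; expected name, description, genes...")
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT line ", i, " ('", f[1], "'): duplicate symbols removed",
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[i]] <- GeneSet(f[1], genes, f[2])
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets list of [GeneSet()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, if (nzchar(s$description)) s$description else ".", s$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
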