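# On-disk formats: Bismark COV, TSS annotation (GTF/BED6), genome FASTA,
# expression matrices (TSV / MatrixMarket), gene-activity TSV.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cpgactivity_validation_error", "error")))
}

abort_parse <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("cpgactivity_parse_error", "error")))
}

#' Per-cell CpG methylation calls
#'
#' A `methylation_calls` object is a `data.table` with columns `chrom`,
#' `pos` (1-based), `n_meth`, `n_unmeth` and a `cell_id` attribute. One
#' row per covered CpG position; every stored position carries at least
#' one read, and `(chrom, pos)` is unique within a cell.
#'
#' @param chrom character chromosome names.
#' @param pos 1-based integer positions.
#' @param n_meth,n_unmeth non-negative read counts.
#' @param cell_id cell identifier.
#' @return A `methylation_calls` object.
#' @export
methylation_calls <- function(cell_id, chrom = character(),
                              pos = integer(), n_meth = integer(),
                              n_unmeth = integer()) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   n_meth = as.integer(n_meth),
                   n_unmeth = as.integer(n_unmeth))
  if (nrow(dt)) {
    if (anyNA(dt))
      abort_validation("NA values in methylation calls for cell '%s'", cell_id)
    if (any(dt$pos < 1L))
      abort_validation("positions must be >= 1 (cell '%s')", cell_id)
    if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L))
      abort_validation("negative counts in cell '%s'", cell_id)
    if (any(dt$n_meth + dt$n_unmeth < 1L))
      abort_validation("records with zero total reads in cell '%s'", cell_id)
    if (anyDuplicated(dt, by = c("chrom", "pos")))
      abort_validation("duplicate (chrom, pos) records in cell '%s'", cell_id)
  }
  setattr(dt, "cell_id", as.character(cell_id))
  setattr(dt, "class", c("methylation_calls", class(dt)))
  dt
}

#' @exportS3Method base::print
print.methylation_calls <- function(x, ...) {
  cat(sprintf("<methylation_calls> cell '%s': %d CpG records on %d sequence(s)\n",
              attr(x, "cell_id"), nrow(x), length(unique(x$chrom))))
  invisible(x)
}

cell_id_of <- function(calls) attr(calls, "cell_id")

#' Read a Bismark coverage (COV) file
#'
#' Bismark COV is 6-column TSV: chromosome, start, end (1-based,
#' inclusive), methylation percentage, count methylated, count
#' unmethylated. The percentage column is ignored; counts are the primary
#' data and rates are recomputed downstream. Gzip-compressed files are
#' accepted.
#'
#' @param path path to a `.cov` or `.cov.gz` file.
#' @param cell_id cell identifier; defaults to the file name stem.
#' @return A [methylation_calls] object.
#' @export
read_bismark_cov <- function(path, cell_id = NULL) {
  if (!file.exists(path)) abort_validation("COV file not found: %s", path)
  if (is.null(cell_id)) {
    cell_id <- basename(path)
    cell_id <- sub("\\.gz$", "", cell_id)
    cell_id <- sub("\\.(cov|txt|tsv)$", "", cell_id)
  }
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(methylation_calls(cell_id))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    abort_parse("%s: line %d has %d fields, expected 6 (tab-separated)",
                path, which(nf != 6L)[1L], nf[nf != 6L][1L])
  m <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2L]))
  nm <- suppressWarnings(as.integer(m[, 5L]))
  nu <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(pos) | is.na(nm) | is.na(nu))
  if (length(bad))
    abort_parse("%s: line %d is not numeric in columns 2/5/6", path, bad[1L])
  if (any(nm < 0L | nu < 0L))
    abort_validation("%s: negative counts at line %d", path,
                     which(nm < 0L | nu < 0L)[1L])
  methylation_calls(cell_id, chrom = m[, 1L], pos = pos,
                    n_meth = nm, n_unmeth = nu)
}

#' Write methylation calls in Bismark COV format
#'
#' @param calls a [methylation_calls] object.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_bismark_cov <- function(calls, path) {
  stopifnot(inherits(calls, "methylation_calls"))
  tot <- calls$n_meth + calls$n_unmeth
  pct <- ifelse(tot > 0, 100 * calls$n_meth / tot, 0)
  out <- data.table(calls$chrom, calls$pos, calls$pos,
                    formatC(pct, format = "f", digits = 6),
                    calls$n_meth, calls$n_unmeth)
  fwrite(out, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a manifest of per-cell COV files
#'
#' The manifest is a 2-column TSV (`cell_id`, `path`) with a header;
#' relative paths are resolved against the manifest's directory.
#'
#' @param path manifest TSV.
#' @return A named list of [methylation_calls], one per cell.
#' @export
read_cov_manifest <- function(path) {
  if (!file.exists(path)) abort_validation("manifest not found: %s", path)
  man <- fread(path, header = TRUE)
  if (ncol(man) < 2L)
    abort_parse("manifest must have columns cell_id and path: %s", path)
  setnames(man, 1:2, c("cell_id", "path"))
  if (!nrow(man)) abort_validation("manifest is empty: %s", path)
  paths <- ifelse(file.exists(man$path), man$path,
                  file.path(dirname(path), man$path))
  calls <- Map(read_bismark_cov, paths, man$cell_id)
  names(calls) <- man$cell_id
  calls
}

#' Read gene TSS annotation from GTF or BED6
#'
#' For GTF only `gene`-typed features are used; the TSS is the feature
#' start on `+` and the feature end on `-` (GTF is 1-based inclusive).
#' For BED6 the TSS is `start + 1` on `+` and `end` on `-`. Duplicate
#' gene ids collapse to the first record with a warning.
#'
#' @param path annotation file (optionally gzipped).
#' @param format `"gtf"` or `"bed"`; guessed from the extension by default.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @export
read_tss_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed" else "gtf"
  if (!file.exists(path)) abort_validation("annotation not found: %s", path)
  if (file.size(path) == 0)
    abort_validation("empty annotation: %s", path)
  if (format == "gtf") {
    dt <- fread(path, sep = "\t", header = FALSE, quote = "",
                col.names = c("chrom", "source", "type", "start", "end",
                              "score", "strand", "frame", "attributes"))
    dt <- dt[dt$type == "gene", ]
    if (!nrow(dt)) abort_validation("no gene-typed features in %s", path)
    # gene_id "X"; / gene_id X; both tolerated
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?;?.*', "\\1", dt$attributes)
    tss <- ifelse(dt$strand == "+", dt$start, dt$end)
    ann <- data.frame(gene_id = gid, chrom = as.character(dt$chrom),
                      tss = as.integer(tss), strand = as.character(dt$strand),
                      stringsAsFactors = FALSE)
  } else {
    dt <- fread(path, sep = "\t", header = FALSE)
    if (ncol(dt) < 6L)
      abort_parse("BED annotation must have 6 columns (name, strand): %s", path)
    setnames(dt, 1:6, c("chrom", "start", "end", "name", "score", "strand"))
    if (!nrow(dt)) abort_validation("empty annotation: %s", path)
    tss <- ifelse(dt$strand == "+", dt$start + 1L, dt$end)
    ann <- data.frame(gene_id = as.character(dt$name),
                      chrom = as.character(dt$chrom),
                      tss = as.integer(tss), strand = as.character(dt$strand),
                      stringsAsFactors = FALSE)
  }
  if (!all(ann$strand %in% c("+", "-")))
    abort_validation("strand must be '+' or '-' for every gene in %s", path)
  if (anyDuplicated(ann$gene_id)) {
    warning(sprintf("%d duplicate gene_id(s) in %s; keeping first occurrence",
                    sum(duplicated(ann$gene_id)), path))
    ann <- ann[!duplicated(ann$gene_id), ]
  }
  rownames(ann) <- NULL
  ann
}

#' Read a genome FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return A [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort_validation("genome FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read an expression matrix (genes x cells)
#'
#' TSV: first column gene ids, header row of cell ids. MatrixMarket:
#' `path` is the `.mtx` file and `row_names` / `col_names` are one-id-per-
#' line label files.
#'
#' @param path matrix file.
#' @param format `"tsv"` or `"mtx"` (guessed from extension by default).
#' @param row_names,col_names label files, required for `"mtx"`.
#' @return A numeric matrix with gene rownames and cell colnames.
#' @export
read_expression_matrix <- function(path, format = c("auto", "tsv", "mtx"),
                                   row_names = NULL, col_names = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "tsv"
  if (format == "mtx") {
    if (is.null(row_names) || is.null(col_names))
      abort_validation("MTX input needs row_names and col_names label files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(row_names)
    colnames(m) <- readLines(col_names)
    return(m)
  }
  dt <- fread(path, header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  storage.mode(m) <- "double"
  m
}

#' Normalize raw counts to the bounded log-CPM scale
#'
#' Counts are scaled to counts-per-million within each cell, transformed
#' as `log2(CPM + 1)`, and divided by the maximum log value over the whole
#' dataset so that values lie in `[0, 1]` and training and test sets are
#' on a common scale. The training maximum is stored in the
#' `"max_log_expr"` attribute; pass it as `max_log` to place a test set on
#' the training scale.
#'
#' @param counts genes x cells matrix of raw non-negative counts.
#' @param max_log optional normalization constant from a training set.
#' @return Normalized matrix with attribute `max_log_expr`.
#' @export
normalize_expression <- function(counts, max_log = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort_validation("negative counts in expression matrix")
  totals <- colSums(counts)
  if (any(totals == 0))
    abort_validation("cell '%s' has zero total counts",
                     colnames(counts)[which(totals == 0)[1L]] %||%
                       as.character(which(totals == 0)[1L]))
  cpm <- sweep(counts, 2L, totals, "/") * 1e6
  lg <- log2(cpm + 1)
  if (is.null(max_log)) max_log <- max(lg)
  if (max_log <= 0) abort_validation("non-positive normalization constant")
  out <- lg / max_log
  attr(out, "max_log_expr") <- max_log
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a gene-activity matrix
#'
#' Plain TSV with gene rows, a `gene_id` first column and a header row of
#' cell ids; values printed with 6 decimal places so a write/read
#' round-trip is exact at that precision.
#'
#' @param matrix genes x cells numeric matrix with dimnames.
#' @param path output TSV.
#' @return `path` (write) or the matrix (read).
#' @export
write_gene_activity <- function(matrix, path) {
  if (is.null(dim(matrix)) || any(dim(matrix) == 0L))
    abort_validation("gene-activity matrix is empty")
  dt <- data.table(gene_id = rownames(matrix) %||%
                     paste0("gene", seq_len(nrow(matrix))))
  vals <- apply(matrix, 2L, function(v) formatC(v, format = "f", digits = 6))
  vals <- matrix(vals, nrow = nrow(matrix))
  colnames(vals) <- colnames(matrix) %||% paste0("cell", seq_len(ncol(matrix)))
  fwrite(cbind(dt, as.data.table(vals)), path, sep = "\t")
  invisible(path)
}

#' @rdname write_gene_activity
#' @export
read_gene_activity <- function(path) {
  read_expression_matrix(path, format = "tsv")
}
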