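#' Expression study container
#'
#' Bundles a log2 gene-by-sample expression matrix with per-sample design
#' factors.  This is the input object for all two-group contrasts: the
#' matrix rows are gene symbols, the columns samples, and the metadata
#' records strain (`sensitive`/`resistant`), tissue (`mammary`/`blood`),
#' dose group (`sham`/`LD`/`HD`), sampling time (`early`/`late`/`baseline`)
#' and replicate number.
#'
#' @param values numeric matrix, genes x samples, log2 intensity scale,
#'   with unique rownames (gene symbols) and colnames (sample ids).
#' @param sample_meta data.frame with one row per sample and columns
#'   `sample_id`, `strain`, `tissue`, `dose`, `time`, `replicate`.
#'   Row order must match the matrix columns.
#' @return An object of class `expression_study`: a list with elements
#'   `values` and `samples`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("Parp3", "Msh5"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                    strain = "sensitive", tissue = "mammary",
#'                    dose = "sham", time = "baseline", replicate = 1:3)
#' study <- expression_study(m, meta)
#' @export
expression_study <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ldsig("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ldsig("`values` must have gene rownames and sample colnames")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop_ldsig("duplicate gene symbol(s): %s",
               paste(unique(dup), collapse = ", "))
  }
  if (!all(is.finite(values))) stop_ldsig("expression values must be finite")
  required <- c("sample_id", "strain", "tissue", "dose", "time", "replicate")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols)) {
    stop_ldsig("sample metadata lacks column(s): %s",
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(sample_meta) != ncol(values)) {
    stop_ldsig("metadata has %d rows but matrix has %d samples",
               nrow(sample_meta), ncol(values))
  }
  missing_meta <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(missing_meta)) {
    stop_ldsig("no metadata for sample(s): %s",
               paste(missing_meta, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, samples = sample_meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("factors:",
      sprintf("strain{%s}", paste(unique(x$samples$strain), collapse = ",")),
      sprintf("tissue{%s}", paste(unique(x$samples$tissue), collapse = ",")),
      sprintf("dose{%s}",   paste(unique(x$samples$dose), collapse = ",")),
      sprintf("time{%s}",   paste(unique(x$samples$time), collapse = ",")),
      "\n")
  invisible(x)
}

#' Read / write an expression study as TSV
#'
#' The matrix file is tab-separated with a header row of sample ids and a
#' first column of gene symbols; the metadata file is keyed by `sample_id`.
#' Sample order follows the matrix header.  Values are parsed with "."
#' decimal separator; a non-numeric cell raises an error naming the row and
#' column.
#'
#' @param matrix_path,meta_path paths to the expression matrix TSV and the
#'   sample metadata TSV.
#' @return [read_expression_study()] returns an `expression_study`.
#' @export
read_expression_study <- function(matrix_path, meta_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop_ldsig("matrix file needs gene column + samples")
  genes <- raw[[1L]]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop_ldsig("duplicate gene symbol(s) in %s: %s", matrix_path,
               paste(dup, collapse = ", "))
  }
  num <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L)
  for (j in seq_len(ncol(raw) - 1L)) {
    col <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(col) & !is.na(raw[[j + 1L]]))
    if (length(bad)) {
      stop_ldsig("non-numeric value '%s' at gene '%s', sample '%s'",
                 raw[[j + 1L]][bad[1L]], genes[bad[1L]],
                 names(raw)[j + 1L])
    }
    num[, j] <- col
  }
  dimnames(num) <- list(genes, names(raw)[-1L])
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            colClasses = "character")
  meta$replicate <- as.integer(meta$replicate)
  expression_study(num, meta)
}

#' @rdname read_expression_study
#' @param study an `expression_study`.
#' @export
write_expression_study <- function(study, matrix_path, meta_path) {
  stopifnot(inherits(study, "expression_study"))
  tab <- data.frame(gene = rownames(study$values),
                    study$values, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

# Logical sample selector from a named filter list, e.g.
# list(strain = "sensitive", dose = c("sham"), tissue = "blood").
sample_filter <- function(study, filter) {
  keep <- rep(TRUE, nrow(study$samples))
  for (nm in names(filter)) {
    if (!nm %in% names(study$samples)) {
      stop_ldsig("unknown sample factor '%s'", nm)
    }
    keep <- keep & study$samples[[nm]] %in% filter[[nm]]
  }
  keep
}
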