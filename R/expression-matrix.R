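#' Expression matrix with sample-to-population annotation
#'
#' The central container of the package: a gene x sample matrix of
#' non-negative expression values together with a sample annotation table
#' mapping each sample to a cell population, an acquisition order (used when
#' analyses restrict to the most recently acquired replicates), and a
#' neuronal/nonneuronal flag per sample. The measurement unit is recorded so
#' downstream stages can transform (or refuse to transform) appropriately.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). All values must be non-negative and finite.
#' @param sample_population Named character vector or factor mapping every
#'   column of `values` to a population label.
#' @param sample_order Optional named numeric vector: per-sample acquisition
#'   rank; larger means more recent. Defaults to column position.
#' @param is_neuronal Optional named logical vector per sample. Defaults to
#'   `TRUE` for all samples.
#' @param unit One of `"count"`, `"fpkm"`, `"cpm"`, `"log2fpkm1"`,
#'   `"log2cpm1"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `samples` (data.frame with columns `sample`, `population`,
#'   `order`, `is_neuronal`), and `unit`.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- ExpressionMatrix(m, c(s1 = "A", s2 = "A", s3 = "B", s4 = "B"))
#' populations(em)
#' @export
ExpressionMatrix <- function(values, sample_population, sample_order = NULL,
                             is_neuronal = NULL,
                             unit = c("count", "fpkm", "cpm",
                                      "log2fpkm1", "log2cpm1")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative", call. = FALSE)

  smp <- colnames(values)
  sample_population <- as.character(sample_population)[match_samples(
    sample_population, smp, "sample_population")]
  names(sample_population) <- smp
  if (anyNA(sample_population))
    stop("every sample must map to exactly one population", call. = FALSE)

  if (is.null(sample_order)) {
    sample_order <- seq_along(smp)
    names(sample_order) <- smp
  } else {
    sample_order <- sample_order[match_samples(sample_order, smp,
                                               "sample_order")]
  }
  if (is.null(is_neuronal)) {
    is_neuronal <- rep(TRUE, length(smp))
    names(is_neuronal) <- smp
  } else {
    is_neuronal <- is_neuronal[match_samples(is_neuronal, smp, "is_neuronal")]
  }

  structure(
    list(
      values = values,
      samples = data.frame(
        sample = smp,
        population = unname(sample_population),
        order = unname(as.numeric(sample_order)),
        is_neuronal = unname(as.logical(is_neuronal)),
        stringsAsFactors = FALSE
      ),
      unit = unit
    ),
    class = "ExpressionMatrix"
  )
}

# Align a named per-sample vector to the matrix columns.
match_samples <- function(x, samples, what) {
  if (is.null(names(x))) {
    if (length(x) != length(samples))
      stop("'", what, "' must be named or have one entry per sample",
           call. = FALSE)
    return(seq_along(samples))
  }
  idx <- match(samples, names(x))
  if (anyNA(idx))
    stop("samples missing from '", what, "': ",
         paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d populations), unit = %s\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$population)), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Population labels of an ExpressionMatrix or PopulationMatrix
#' @param x An `ExpressionMatrix` or `PopulationMatrix`.
#' @return Character vector of population labels (in first-appearance order
#'   for an `ExpressionMatrix`).
#' @export
populations <- function(x) {
  if (inherits(x, "PopulationMatrix")) return(colnames(x$values))
  unique(x$samples$population)
}

#' Read an expression matrix with its annotation tables
#'
#' Reads a gene x sample matrix either from a tab-delimited file (gene ids in
#' the first column, sample ids in the header) or from a MatrixMarket triplet
#' file accompanied by plain-text gene and sample id listings. The sample
#' annotation table must contain columns `sample` and `population`; optional
#' columns `order` (numeric acquisition rank) and `is_neuronal` (logical) are
#' used when present. Samples present in the matrix but absent from the
#' annotation are an error.
#'
#' @param matrix_path Path to the TSV matrix, or to a `.mtx` file.
#' @param samples_path Path to the tab-delimited sample annotation table.
#' @param genes_path For the MatrixMarket route, path to a file with one gene
#'   id per line (row order); ignored for TSV input. A matching
#'   one-sample-id-per-line file is expected at `samples_ids_path` when the
#'   annotation table order does not define column order.
#' @param samples_ids_path Optional path listing sample ids in matrix column
#'   order (MatrixMarket route). Defaults to the `sample` column order of the
#'   annotation table.
#' @param unit Measurement unit of the stored values.
#' @return An [ExpressionMatrix()].
#' @export
load_expression <- function(matrix_path, samples_path, genes_path = NULL,
                            samples_ids_path = NULL, unit = "count") {
  ann <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  req <- c("sample", "population")
  if (!all(req %in% names(ann)))
    stop("sample table must have columns 'sample' and 'population'",
         call. = FALSE)

  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(genes_path))
      stop("MatrixMarket input requires 'genes_path'", call. = FALSE)
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    smp <- if (!is.null(samples_ids_path)) {
      ids <- readLines(samples_ids_path)
      ids[nzchar(ids)]
    } else {
      ann$sample
    }
    m <- as.matrix(Matrix::readMM(matrix_path))
    if (nrow(m) != length(genes) || ncol(m) != length(smp))
      stop("matrix dimensions do not match gene/sample id listings",
           call. = FALSE)
    dimnames(m) <- list(genes, smp)
  } else {
    tab <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    genes <- as.character(tab[[1L]])
    if (anyDuplicated(genes))
      stop("duplicate gene identifiers in matrix", call. = FALSE)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- genes
  }

  idx <- match(colnames(m), ann$sample)
  if (anyNA(idx))
    stop("samples absent from annotation table: ",
         paste(colnames(m)[is.na(idx)], collapse = ", "), call. = FALSE)
  ann <- ann[idx, , drop = FALSE]

  ExpressionMatrix(
    m,
    sample_population = stats::setNames(ann$population, ann$sample),
    sample_order = if ("order" %in% names(ann))
      stats::setNames(ann$order, ann$sample),
    is_neuronal = if ("is_neuronal" %in% names(ann))
      stats::setNames(as.logical(ann$is_neuronal), ann$sample),
    unit = unit
  )
}

#' Write an ExpressionMatrix and its sample table to TSV files
#'
#' @param em An [ExpressionMatrix()].
#' @param matrix_path,samples_path Output paths.
#' @return Invisibly, `em`.
#' @export
write_expression <- function(em, matrix_path, samples_path) {
  tab <- data.frame(gene = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(em$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(em)
}

#' Convert raw counts to FPKM
#'
#' FPKM = count / (gene length in kb) / (library size in millions), the
#' library size being the per-sample total count over all genes present in
#' the matrix.
#'
#' @param counts An [ExpressionMatrix()] with unit `"count"`.
#' @param gene_table A [gene_table()] providing a length (bp) for every gene.
#' @return An `ExpressionMatrix` with unit `"fpkm"`.
#' @export
to_fpkm <- function(counts, gene_table) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "count")
    stop("to_fpkm requires unit 'count', got '", counts$unit, "'",
         call. = FALSE)
  len <- gene_table$length[match(rownames(counts$values), gene_table$gene)]
  if (anyNA(len))
    stop("gene lengths missing for: ",
         paste(utils::head(rownames(counts$values)[is.na(len)]),
               collapse = ", "), call. = FALSE)
  lib <- colSums(counts$values)
  if (any(lib == 0)) stop("zero library size", call. = FALSE)
  out <- counts
  out$values <- counts$values / (len / 1000) /
    rep(lib / 1e6, each = nrow(counts$values))
  out$unit <- "fpkm"
  out
}

#' Convert raw counts to CPM or log2(CPM + 1)
#'
#' @param counts An [ExpressionMatrix()] with unit `"count"`.
#' @param log If `TRUE`, return log2(CPM + 1) with unit `"log2cpm1"`.
#' @return An `ExpressionMatrix` with unit `"cpm"` or `"log2cpm1"`.
#' @export
to_cpm <- function(counts, log = FALSE) {
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (counts$unit != "count")
    stop("to_cpm requires unit 'count', got '", counts$unit, "'",
         call. = FALSE)
  lib <- colSums(counts$values)
  if (any(lib == 0)) stop("zero library size", call. = FALSE)
  out <- counts
  out$values <- counts$values / rep(lib / 1e6, each = nrow(counts$values))
  out$unit <- "cpm"
  if (log) {
    out$values <- log2p1(out$values)
    out$unit <- "log2cpm1"
  }
  out
}

#' Replicate-averaged population profiles
#'
#' Averages replicates within each population, optionally after a
#' log2(x + 1) transform and optionally restricted to the most recently
#' acquired replicates (highest `order`), the convention used to equalize
#' statistical power across populations profiled at different depths.
#'
#' @param em An [ExpressionMatrix()].
#' @param log_transform Apply log2(x + 1) before averaging. Ignored (with no
#'   effect) when the unit is already on a log scale.
#' @param max_replicates If not `NULL`, use at most this many replicates per
#'   population, chosen by highest acquisition order.
#' @return A `PopulationMatrix`: list with `values` (gene x population means),
#'   `n_replicates`, `is_neuronal` (per population), and `log2` flag.
#' @export
population_means <- function(em, log_transform = FALSE,
                             max_replicates = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  pops <- populations(em)
  v <- em$values
  already_log <- em$unit %in% c("log2fpkm1", "log2cpm1")
  if (log_transform && !already_log) v <- log2p1(v)

  keep <- unlist(lapply(pops, function(p) {
    rows <- which(em$samples$population == p)
    if (length(rows) == 0L) stop("population with zero samples: ", p,
                                 call. = FALSE)
    if (!is.null(max_replicates) && length(rows) > max_replicates) {
      rows <- rows[order(em$samples$order[rows],
                         decreasing = TRUE)][seq_len(max_replicates)]
    }
    rows
  }))
  sel <- em$samples[keep, , drop = FALSE]
  vals <- sapply(pops, function(p) {
    rowMeans(v[, keep[sel$population == p], drop = FALSE])
  })
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(rownames(v), pops))
  neuro <- vapply(pops, function(p) all(sel$is_neuronal[sel$population == p]),
                  logical(1))
  structure(
    list(values = vals,
         n_replicates = stats::setNames(
           as.integer(table(sel$population)[pops]), pops),
         is_neuronal = neuro,
         log2 = already_log || log_transform),
    class = "PopulationMatrix"
  )
}

#' Construct a PopulationMatrix from cluster-average profiles
#'
#' For reference datasets distributed only as cluster averages (no
#' replicate structure), or for building fixtures directly.
#'
#' @param values Gene x population numeric matrix with dimnames.
#' @param n_replicates Optional named integer vector per population
#'   (defaults to 1).
#' @param is_neuronal Optional named logical vector per population
#'   (defaults to `TRUE`).
#' @param log2 Whether `values` are already on a log2(x + 1) scale.
#' @return A `PopulationMatrix`.
#' @export
population_matrix <- function(values, n_replicates = NULL,
                              is_neuronal = NULL, log2 = FALSE) {
  if (!is.matrix(values) || is.null(rownames(values)) ||
      is.null(colnames(values)))
    stop("'values' must be a matrix with gene and population dimnames",
         call. = FALSE)
  pops <- colnames(values)
  n_replicates <- n_replicates %||% stats::setNames(rep(1L, length(pops)),
                                                    pops)
  is_neuronal <- is_neuronal %||% stats::setNames(rep(TRUE, length(pops)),
                                                  pops)
  structure(list(values = values, n_replicates = n_replicates[pops],
                 is_neuronal = stats::setNames(as.logical(is_neuronal[pops]),
                                               pops),
                 log2 = isTRUE(log2)),
            class = "PopulationMatrix")
}

#' @export
print.PopulationMatrix <- function(x, ...) {
  cat(sprintf("PopulationMatrix: %d genes x %d populations (log2 = %s)\n",
              nrow(x$values), ncol(x$values), x$log2))
  invisible(x)
}

#' Per-gene annotation table
#'
#' @param gene Character vector of unique gene ids.
#' @param length Positive integer gene lengths in bp.
#' @param ... Further per-gene columns (recycled by `data.frame`).
#' @return A data.frame of class `gene_table`.
#' @export
gene_table <- function(gene, length, ...) {
  if (anyDuplicated(gene)) stop("duplicate gene ids", call. = FALSE)
  if (any(length < 1)) stop("gene lengths must be >= 1 bp", call. = FALSE)
  structure(data.frame(gene = as.character(gene), length = as.numeric(length),
                       ..., stringsAsFactors = FALSE),
            class = c("gene_table", "data.frame"))
}

#' Read a per-gene annotation table (TSV with columns gene, length, ...)
#' @param path File path.
#' @return A [gene_table()].
#' @export
load_gene_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "length") %in% names(tab)))
    stop("gene table needs columns 'gene' and 'length'", call. = FALSE)
  do.call(gene_table, tab)
}
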