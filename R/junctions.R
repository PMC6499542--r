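#' Splice-junction count table
#'
#' One record per sample x junction. Coordinates are 0-based half-open; the
#' strand determines which end of the junction is the donor, so `donor` and
#' `acceptor` are stored explicitly rather than as start/end.
#'
#' @param sample Sample ids.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"`.
#' @param donor,acceptor Integer genomic positions.
#' @param count Non-negative read counts.
#' @param gene Optional gene id per junction (`NA` allowed).
#' @return A data.frame of class `junction_table`.
#' @export
junction_table <- function(sample, chrom, strand, donor, acceptor, count,
                           gene = NA_character_) {
  if (any(count < 0)) stop("junction counts must be >= 0", call. = FALSE)
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  jt <- data.frame(sample = as.character(sample), chrom = as.character(chrom),
                   strand = as.character(strand),
                   donor = as.integer(donor), acceptor = as.integer(acceptor),
                   count = as.numeric(count), gene = as.character(gene),
                   stringsAsFactors = FALSE)
  key <- paste(jt$sample, jt$chrom, jt$strand, jt$donor, jt$acceptor)
  if (anyDuplicated(key))
    stop("duplicate (sample, chrom, strand, donor, acceptor) records",
         call. = FALSE)
  structure(jt, class = c("junction_table", "data.frame"))
}

#' Read a junction table from TSV
#'
#' Expected columns: `sample`, `chrom`, `strand`, `donor`, `acceptor`,
#' `count`, and optionally `gene`.
#'
#' @param path File path.
#' @return A [junction_table()].
#' @export
load_junctions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "strand", "donor", "acceptor", "count")
  if (!all(req %in% names(tab)))
    stop("junction table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  junction_table(tab$sample, tab$chrom, tab$strand, tab$donor, tab$acceptor,
                 tab$count, if ("gene" %in% names(tab)) tab$gene else NA)
}

#' Write a junction table to TSV
#' @param jt A [junction_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junctions <- function(jt, path) {
  utils::write.table(jt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
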