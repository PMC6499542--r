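#' Read gene families from a GMT file
#'
#' Standard GMT layout: one family per line, tab-separated fields
#' `name`, `description`, then member gene ids. Duplicate members within a
#' line are collapsed; lines with no members are skipped with a warning.
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector; when given, family members are
#'   intersected with it and emptied families dropped.
#' @param source_tag Optional provenance label stored on the result.
#' @return A named list of character vectors of class `gene_families`, with
#'   attribute `source`.
#' @export
load_gene_families <- function(path, universe = NULL, source_tag = path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fams <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(parts) < 3L || length(members) == 0L) {
      warning("skipping GMT line with no members: ", parts[1L], call. = FALSE)
      next
    }
    fams[[parts[1L]]] <- members
  }
  if (!is.null(universe)) {
    fams <- lapply(fams, intersect, y = universe)
    fams <- fams[lengths(fams) > 0L]
  }
  structure(fams, class = "gene_families", source = source_tag)
}

#' Write gene families to a GMT file
#'
#' @param fams Named list of character vectors (or `gene_families`).
#' @param path Output path.
#' @param description Description field written for every family.
#' @return Invisibly, `path`.
#' @export
write_gene_families <- function(fams, path, description = "na") {
  lines <- vapply(names(fams), function(nm) {
    paste(c(nm, description, fams[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
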