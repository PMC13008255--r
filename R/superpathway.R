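#' Construct a superpathway
#'
#' A superpathway is a pathway gene set partitioned into per-cell-type gene
#' subsets: the unit of analysis for recapitulation scoring. Each cell type
#' `b` carries a subset of the pathway's genes; the full pathway gene set is
#' the union of the per-cell-type subsets.
#'
#' @param pathway_id Character scalar naming the pathway.
#' @param gene_sets Named list, one character vector of human gene symbols per
#'   cell type. Symbols are uppercased; empty subsets are dropped with a
#'   warning.
#' @return An object of class `superpathway`: a list with `pathway_id`,
#'   `gene_sets` (named list) and `genes` (the union).
#' @export
#' @examples
#' superpathway("JAK_STAT", list(Tcell = c("IL13", "IL7"), KC = c("IL15")))
superpathway <- function(pathway_id, gene_sets) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1)
  if (is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("`gene_sets` must be a named list keyed by cell type.")
  }
  gene_sets <- map(gene_sets, ~ unique(toupper(as.character(.x))))
  empty <- map_dbl(gene_sets, length) == 0
  if (any(empty)) {
    warn(paste0(
      "Dropping cell types with empty gene subsets: ",
      paste(names(gene_sets)[empty], collapse = ", ")
    ))
    gene_sets <- gene_sets[!empty]
  }
  if (length(gene_sets) == 0) {
    abort("All gene subsets are empty; a superpathway needs at least one gene.")
  }
  structure(
    list(
      pathway_id = pathway_id,
      gene_sets = gene_sets,
      genes = unique(unlist(gene_sets, use.names = FALSE))
    ),
    class = "superpathway"
  )
}

#' @export
print.superpathway <- function(x, ...) {
  cat(
    "<superpathway> ", x$pathway_id, ": ", length(x$genes), " genes across ",
    length(x$gene_sets), " cell types\n",
    sep = ""
  )
  for (ct in names(x$gene_sets)) {
    cat("  ", ct, ": ", length(x$gene_sets[[ct]]), " genes\n", sep = "")
  }
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Parses the tab-separated GMT interchange format (one gene set per line:
#' name, description, genes...). Gene symbols are uppercased and duplicates
#' within a line removed; lines with fewer than three fields are skipped with
#' a warning. Order of pathways and of genes within a pathway is preserved.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `pathway_id` and `gene`, one row per
#'   (pathway, gene) pair, in file order.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(pathway_id = character(0), gene = character(0)))
  }
  parsed <- map(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      warn(paste0("Skipping GMT line with fewer than 3 fields: ", substr(line, 1, 40)))
      return(NULL)
    }
    genes <- unique(toupper(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    tibble(pathway_id = fields[[1]], gene = genes)
  })
  bind_rows(parsed)
}

#' Split a pathway gene list into a superpathway
#'
#' Convenience constructor assigning the same pathway gene set (or supplied
#' subsets) to each cell type under analysis.
#'
#' @param gmt Tibble as returned by [read_gmt()], or character vector of genes.
#' @param pathway_id Pathway to extract when `gmt` is a tibble.
#' @param cell_types Character vector of cell types; each receives the full
#'   gene set unless `subsets` is given.
#' @param subsets Optional named list of cell type -> gene subset overriding
#'   the default full assignment.
#' @return A [superpathway] object.
#' @export
as_superpathway <- function(gmt, pathway_id, cell_types, subsets = NULL) {
  genes <- if (is.data.frame(gmt)) {
    gmt$gene[gmt$pathway_id == pathway_id]
  } else {
    as.character(gmt)
  }
  if (length(genes) == 0) {
    abort(paste0("No genes found for pathway '", pathway_id, "'."))
  }
  sets <- if (is.null(subsets)) {
    setNames(rep(list(genes), length(cell_types)), cell_types)
  } else {
    subsets
  }
  superpathway(pathway_id, sets)
}
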