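#' Orthogroup tables
#'
#' An orthogroup groups genes across genomes that descend from one ancestral
#' gene; it is the unit of cross-genome gene equivalence used to rewrite
#' gene-reaction rules. Tables are consumed in the OrthoFinder
#' `Orthogroups.tsv` dialect -- orthology inference itself is upstream of this
#' package.
#'
#' @param orthogroups named list: orthogroup id -> named list of genome id ->
#'   character vector of gene ids.
#' @param genomes character vector of genome ids (column order).
#' @return object of class `orthogroup_table` with a `(genome, gene) ->
#'   orthogroup` index.
#' @export
orthogroup_table <- function(orthogroups, genomes) {
  gene_index <- lapply(stats::setNames(genomes, genomes), function(g) character())
  for (og in names(orthogroups)) {
    for (gn in names(orthogroups[[og]])) {
      genes <- orthogroups[[og]][[gn]]
      if (length(genes) == 0L) next
      dup <- intersect(genes, names(gene_index[[gn]]))
      dup <- c(dup, genes[duplicated(genes)])
      if (length(dup)) {
        stop("gene '", dup[[1L]], "' of genome '", gn,
             "' appears in more than one orthogroup", call. = FALSE)
      }
      gene_index[[gn]][genes] <- og
    }
  }
  structure(list(orthogroups = orthogroups, genomes = genomes,
                 gene_index = gene_index),
            class = "orthogroup_table")
}

#' @export
print.orthogroup_table <- function(x, ...) {
  cat("<orthogroup_table> ", length(x$orthogroups), " orthogroups x ",
      length(x$genomes), " genomes\n", sep = "")
  invisible(x)
}

og_lookup <- function(table, genome, gene) {
  og <- table$gene_index[[genome]][gene]
  if (is.null(og) || is.na(og)) NA_character_ else unname(og)
}

#' Read an OrthoFinder orthogroup table
#'
#' Parses the `Orthogroups.tsv` dialect: a header line with the orthogroup
#' column followed by one column per genome; cells are comma-plus-space
#' separated gene (or protein) id lists; empty cells mean no member in that
#' genome. If `idmap` is given, protein ids are translated to gene ids;
#' proteins with no mapping are dropped from the table and reported in the
#' `unmapped_proteins` attribute (a data frame genome/protein), never silently
#' kept.
#'
#' @param path TSV file path.
#' @param idmap optional [read_idmap()] result (named list genome -> named
#'   character vector protein id -> gene id).
#' @return an [orthogroup_table]; attribute `unmapped_proteins` lists
#'   protein ids that could not be translated.
#' @export
read_orthogroups <- function(path, idmap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 1L) stop("empty orthogroup table: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  genomes <- trimws(header[-1L])
  ncol_expected <- length(header)
  ogs <- list()
  unmapped <- list()
  for (ln in seq_along(lines)[-1L]) {
    cells <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(cells) < ncol_expected) {
      cells <- c(cells, rep("", ncol_expected - length(cells)))
    } else if (length(cells) > ncol_expected) {
      stop("ragged orthogroup table row at line ", ln, ": ",
           length(cells), " columns, expected ", ncol_expected, call. = FALSE)
    }
    og_id <- trimws(cells[[1L]])
    row <- stats::setNames(vector("list", length(genomes)), genomes)
    for (j in seq_along(genomes)) {
      cell <- trimws(cells[[j + 1L]])
      ids <- if (nzchar(cell)) trimws(strsplit(cell, ",", fixed = TRUE)[[1L]])
             else character()
      ids <- ids[nzchar(ids)]
      if (!is.null(idmap)) {
        map <- idmap[[genomes[[j]]]]
        mapped <- if (is.null(map)) rep(NA_character_, length(ids)) else
          unname(map[ids])
        lost <- ids[is.na(mapped)]
        if (length(lost)) {
          unmapped[[length(unmapped) + 1L]] <- data.frame(
            genome = genomes[[j]], protein = lost, stringsAsFactors = FALSE)
        }
        ids <- mapped[!is.na(mapped)]
      }
      row[[j]] <- ids
    }
    ogs[[og_id]] <- row
  }
  tab <- orthogroup_table(ogs, genomes)
  attr(tab, "unmapped_proteins") <- if (length(unmapped))
    do.call(rbind, unmapped) else
    data.frame(genome = character(), protein = character(),
               stringsAsFactors = FALSE)
  if (nrow(attr(tab, "unmapped_proteins"))) {
    warning(nrow(attr(tab, "unmapped_proteins")),
            " protein id(s) had no gene mapping and were dropped; see ",
            "attr(, 'unmapped_proteins')", call. = FALSE)
  }
  tab
}

#' Write an orthogroup table in the OrthoFinder dialect
#'
#' @param table an [orthogroup_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(table, path) {
  header <- paste(c("Orthogroup", table$genomes), collapse = "\t")
  rows <- vapply(names(table$orthogroups), function(og) {
    cells <- vapply(table$genomes, function(gn) {
      paste(table$orthogroups[[og]][[gn]], collapse = ", ")
    }, character(1L))
    paste(c(og, cells), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a protein-to-gene identifier map
#'
#' Two-column TSV (`protein_id`, `gene_id`) per genome, as produced from
#' GenBank records. Used to translate OrthoFinder protein ids into the gene
#' ids that gene-reaction rules are written in.
#'
#' @param paths named character vector: genome id -> TSV path.
#' @return named list genome -> named character vector protein id -> gene id.
#' @export
read_idmap <- function(paths) {
  out <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("idmap file '", p, "' needs two columns", call. = FALSE)
    stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  })
  stats::setNames(out, names(paths))
}

og_counts <- function(table) {
  rows <- lapply(table$orthogroups, function(row) {
    vapply(table$genomes, function(gn) length(row[[gn]]), integer(1L))
  })
  cnt <- do.call(rbind, rows)
  rownames(cnt) <- names(table$orthogroups)
  cnt
}

#' Single-copy orthogroups
#'
#' Orthogroups with exactly one gene in every genome of the table -- the
#' classic marker set for species-tree inference.
#'
#' @param table an [orthogroup_table].
#' @return character vector of orthogroup ids.
#' @export
single_copy_orthogroups <- function(table) {
  if (length(table$orthogroups) == 0L) return(character())
  cnt <- og_counts(table)
  rownames(cnt)[apply(cnt == 1L, 1L, all)]
}

#' Core orthogroups
#'
#' Orthogroups with at least one gene in every genome of the table. Every
#' single-copy orthogroup is core.
#'
#' @param table an [orthogroup_table].
#' @return character vector of orthogroup ids.
#' @export
core_orthogroups <- function(table) {
  if (length(table$orthogroups) == 0L) return(character())
  cnt <- og_counts(table)
  rownames(cnt)[apply(cnt >= 1L, 1L, all)]
}
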