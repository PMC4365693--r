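# COG-category aggregation and incremental functional profiles along
# nested clade core-genomes.

COG_LETTERS <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
                 "C", "G", "E", "F", "H", "I", "P", "Q", "R", "S")

COG_SUPER <- list(
  information = c("J", "K", "L"),
  cellular = c("D", "V", "T", "M", "N", "U", "O"),
  metabolism = c("C", "G", "E", "F", "H", "I", "P", "Q"),
  poorly_characterized = c("R", "S"))

#' COG annotation map
#'
#' Maps gene ids to COG category letters. A gene assigned to one or two
#' categories keeps them (and is counted once per category); a gene
#' assigned to more than two collapses to the synthetic letter \code{"X"}
#' (multi-process), which replaces — never joins — the longer list.
#'
#' @param df data.frame with columns \code{gene_id} and \code{categories}
#'   (letters concatenated, e.g. \code{"KL"})
#' @return object of class \code{annotation_map} (named list gene_id ->
#'   character vector of letters)
#' @export
annotation_map <- function(df) {
  stopifnot(is.data.frame(df), all(c("gene_id", "categories") %in% names(df)))
  if (anyDuplicated(df$gene_id)) stop2("duplicate gene ids")
  ann <- lapply(strsplit(as.character(df$categories), ""), function(ls) {
    bad <- setdiff(ls, COG_LETTERS)
    if (length(bad)) stop2("unknown COG category letter: ",
                           paste(bad, collapse = ", "))
    if (length(ls) > 2) "X" else ls
  })
  names(ann) <- df$gene_id
  structure(ann, class = "annotation_map")
}

#' @rdname annotation_map
#' @param path TSV with columns gene_id, categories
#' @export
read_annotation_map <- function(path) {
  annotation_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                   colClasses = "character"))
}

#' Aggregate COG categories over a gene set
#'
#' A gene with two categories increments both (dual counting); a gene
#' collapsed to \code{X} increments \code{X} only; genes absent from the
#' map land in \code{unassigned}.
#'
#' @param genes character vector of gene ids
#' @param ann an \code{\link{annotation_map}}
#' @return list with \code{counts} (named vector over the category
#'   alphabet + X), \code{unassigned} and \code{super} (totals per
#'   super-category)
#' @export
aggregate_categories <- function(genes, ann) {
  stopifnot(inherits(ann, "annotation_map"))
  counts <- stats::setNames(integer(length(COG_LETTERS) + 1),
                            c(COG_LETTERS, "X"))
  unassigned <- 0L
  for (g in genes) {
    ls <- ann[[g]]
    if (is.null(ls)) unassigned <- unassigned + 1L
    else for (l in ls) counts[l] <- counts[l] + 1L
  }
  super <- vapply(COG_SUPER, function(ls) sum(counts[ls]), integer(1))
  list(counts = counts, unassigned = unassigned, super = super)
}

#' Core genes of a clade, projected onto a representative genome
#'
#' CLOGs covering every member of the clade, reduced to the gene ids the
#' representative contributes to them.
#'
#' @param table a \code{\link{clog_table}}
#' @param clade genome ids (subset of the universe)
#' @param representative a genome in the clade
#' @return character vector of the representative's gene ids
#' @export
clade_core_genes <- function(table, clade, representative) {
  stopifnot(inherits(table, "clog_table"))
  clade <- as.character(clade)
  bad <- setdiff(clade, table$genomes)
  if (length(bad)) stop2("not in universe: ", paste(bad, collapse = ", "))
  if (!representative %in% clade)
    stop2("representative must belong to the clade")
  p <- presence_matrix(table)
  core_ids <- table$clog_ids[rowSums(p[, clade, drop = FALSE]) ==
                               length(clade)]
  m <- table$members
  m$gene_id[m$clog_id %in% core_ids & m$genome_id == representative]
}

#' Nested clade chain
#'
#' @param clades list of genome-id vectors, largest first; the first must be
#'   the whole universe and each following set a strict subset of the
#'   previous one
#' @param universe the genome universe
#' @return object of class \code{clade_chain}
#' @export
clade_chain <- function(clades, universe) {
  stopifnot(is.list(clades), length(clades) >= 1)
  clades <- lapply(clades, as.character)
  if (!setequal(clades[[1]], universe))
    stop2("the first clade must equal the genome universe")
  for (i in seq_along(clades)[-1]) {
    if (!all(clades[[i]] %in% clades[[i - 1]]) ||
        length(clades[[i]]) >= length(clades[[i - 1]]))
      stop2("clades must be strictly nested (each a strict subset of the ",
            "previous); violated at step ", i)
  }
  structure(list(clades = clades), class = "clade_chain")
}

#' Incremental functional profile along a clade chain
#'
#' Walks the chain from the whole universe down to the smallest clade.
#' Step i's increment is the representative's clade-core gene set minus the
#' cores of all larger clades; increments are pairwise disjoint and
#' partition the smallest clade's core. Each increment is profiled by COG
#' category; a per-category percent distribution across steps and a
#' two-bin core-vs-clade summary with a transparent classification rule
#' (\code{"core-defined"} when > 2/3 of a category's mass sits at the
#' whole-universe step, \code{"clade-defined"} when > 2/3 sits at clade
#' steps, else \code{"mixed"}) are also returned.
#'
#' @param table a \code{\link{clog_table}}
#' @param chain a \code{\link{clade_chain}} over the table's universe
#' @param representative genome id belonging to the smallest clade
#' @param ann an \code{\link{annotation_map}}
#' @param core_fraction threshold of the classification rule (default 2/3)
#' @return list with \code{increments} (gene sets per step),
#'   \code{category_counts} (matrix step x category), \code{percent}
#'   (per-category distribution across steps, percent),
#'   \code{two_bin} (per category: fraction at the universe step) and
#'   \code{category_class}
#' @export
incremental_profile <- function(table, chain, representative, ann,
                                core_fraction = 2 / 3) {
  stopifnot(inherits(table, "clog_table"), inherits(chain, "clade_chain"),
            inherits(ann, "annotation_map"))
  clades <- chain$clades
  if (!representative %in% clades[[length(clades)]])
    stop2("representative must belong to the smallest clade")
  cores <- lapply(clades, clade_core_genes, table = table,
                  representative = representative)
  increments <- vector("list", length(clades))
  seen <- character()
  for (i in seq_along(clades)) {
    increments[[i]] <- setdiff(cores[[i]], seen)
    seen <- union(seen, cores[[i]])
  }
  names(increments) <- paste0("step", seq_along(clades))
  cats <- t(vapply(increments, function(g)
    aggregate_categories(g, ann)$counts,
    stats::setNames(integer(length(COG_LETTERS) + 1),
                    c(COG_LETTERS, "X"))))
  totals <- colSums(cats)
  percent <- sweep(cats, 2, pmax(totals, 1), "/") * 100
  percent[, totals == 0] <- NA_real_
  universe_frac <- ifelse(totals > 0, cats[1, ] / totals, NA_real_)
  category_class <- ifelse(is.na(universe_frac), NA_character_,
                    ifelse(universe_frac > core_fraction, "core-defined",
                    ifelse(1 - universe_frac > core_fraction,
                           "clade-defined", "mixed")))
  list(increments = increments, category_counts = cats, percent = percent,
       two_bin = universe_frac, category_class = category_class)
}
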