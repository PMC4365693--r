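#' CLOG table: ortholog clusters as a presence/absence structure
#'
#' A CLOG (CLique of Orthologous Genes) table maps cluster ids to their
#' member genes, each member a (genome, gene) pair, over a declared genome
#' universe. It is the central structure for all core/pan-genome analysis:
#' classification, rarefaction, similarity and signature mining all operate
#' on it.
#'
#' @param members data.frame with character columns \code{clog_id},
#'   \code{genome_id}, \code{gene_id}; one row per member gene.
#' @param genomes character vector of genome ids defining the universe
#'   (what "all strains" means for core calls). Defaults to the genomes
#'   observed in \code{members}.
#' @return An object of class \code{clog_table} with components
#'   \code{members}, \code{genomes}, \code{clog_ids}, and integer matrix
#'   \code{gene_counts} (CLOG x genome, number of member genes).
#' @examples
#' tab <- clog_table(data.frame(
#'   clog_id = c("C1", "C1", "C2"),
#'   genome_id = c("A", "B", "A"),
#'   gene_id = c("g1", "g2", "g3")))
#' n_clogs(tab)
#' @export
clog_table <- function(members, genomes = NULL) {
  if (!is.data.frame(members))
    stop2("'members' must be a data.frame")
  need <- c("clog_id", "genome_id", "gene_id")
  if (!all(need %in% names(members)))
    stop2("'members' needs columns: ", paste(need, collapse = ", "))
  members <- data.frame(lapply(members[need], as.character),
                        stringsAsFactors = FALSE)
  if (nrow(members) > 0 && any(members$clog_id == "" | members$genome_id == "" |
                               members$gene_id == ""))
    stop2("empty identifiers are not allowed")
  genomes <- as.character(genomes %||% sort(unique(members$genome_id)))
  if (anyDuplicated(genomes))
    stop2("duplicated genome ids in universe")
  bad <- setdiff(unique(members$genome_id), genomes)
  if (length(bad))
    stop2("members reference genomes outside the universe: ",
          paste(bad, collapse = ", "))
  key <- paste(members$clog_id, members$genome_id, members$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop2("duplicated (clog_id, genome_id, gene_id) member triple")
  gene_key <- paste(members$genome_id, members$gene_id, sep = "\r")
  if (anyDuplicated(gene_key))
    stop2("a (genome_id, gene_id) pair appears in more than one CLOG")

  clog_ids <- unique(members$clog_id)
  if (length(clog_ids)) {
    gene_counts <- table(factor(members$clog_id, levels = clog_ids),
                         factor(members$genome_id, levels = genomes))
    gene_counts <- matrix(as.integer(gene_counts), nrow = length(clog_ids),
                          dimnames = list(clog_ids, genomes))
  } else {
    gene_counts <- matrix(integer(0), nrow = 0, ncol = length(genomes),
                          dimnames = list(NULL, genomes))
  }
  structure(list(members = members, genomes = genomes, clog_ids = clog_ids,
                 gene_counts = gene_counts),
            class = "clog_table")
}

#' @rdname clog_table
#' @param x a \code{clog_table}
#' @export
n_clogs <- function(x) {
  stopifnot(inherits(x, "clog_table"))
  length(x$clog_ids)
}

#' @export
print.clog_table <- function(x, ...) {
  cat("CLOG table:", length(x$clog_ids), "CLOGs,", nrow(x$members),
      "member genes,", length(x$genomes), "genomes\n")
  invisible(x)
}

# logical CLOG x genome presence matrix
presence_matrix <- function(table) {
  stopifnot(inherits(table, "clog_table"))
  table$gene_counts > 0L
}

#' Restrict a CLOG table to a genome subset
#'
#' Keeps only members from the given genomes and shrinks the universe to
#' them; CLOGs left without members are dropped.
#'
#' @param table a \code{clog_table}
#' @param genomes character vector of genome ids (subset of the universe)
#' @return a \code{clog_table} over the reduced universe
#' @export
subset_genomes <- function(table, genomes) {
  stopifnot(inherits(table, "clog_table"))
  bad <- setdiff(genomes, table$genomes)
  if (length(bad))
    stop2("not in universe: ", paste(bad, collapse = ", "))
  keep <- table$members$genome_id %in% genomes
  clog_table(table$members[keep, , drop = FALSE], genomes = genomes)
}

#' Classify CLOGs into core, dispensable and unique
#'
#' A CLOG is \emph{core} when it contains at least one sequence from every
#' genome of the universe, \emph{unique} when all its sequences come from a
#' single genome (singletons and putative paralog families alike), and
#' \emph{dispensable} otherwise (2 to G-1 genomes).
#'
#' @param table a \code{clog_table} with a non-empty genome universe
#' @return object of class \code{clog_classification}: \code{class} (named
#'   factor per CLOG), \code{counts} (core/dispensable/unique totals),
#'   \code{occupancy} (genomes per CLOG), \code{occupancy_histogram}.
#' @export
classify_clogs <- function(table) {
  stopifnot(inherits(table, "clog_table"))
  G <- length(table$genomes)
  if (G == 0L) stop2("genome universe is empty")
  occ <- rowSums(presence_matrix(table))
  cls <- ifelse(occ == G, "core", ifelse(occ == 1L, "unique", "dispensable"))
  cls <- factor(cls, levels = c("core", "dispensable", "unique"))
  names(cls) <- table$clog_ids
  occ <- stats::setNames(as.integer(occ), table$clog_ids)
  hist <- tabulate(occ, nbins = G)
  names(hist) <- as.character(seq_len(G))
  structure(list(class = cls,
                 counts = c(table(cls)),
                 occupancy = occ,
                 occupancy_histogram = hist),
            class = "clog_classification")
}

#' @export
print.clog_classification <- function(x, ...) {
  cat("CLOG classification:",
      sum(x$counts), "CLOGs (",
      x$counts[["core"]], "core,",
      x$counts[["dispensable"]], "dispensable,",
      x$counts[["unique"]], "unique )\n")
  invisible(x)
}

#' Per-genome gene counts by CLOG class
#'
#' Counts the genome's \emph{gene} memberships (not CLOGs) falling in core,
#' dispensable and unique CLOGs; the three counts sum to the genome's total
#' clustered genes.
#'
#' @param table a \code{clog_table}
#' @param classification result of \code{\link{classify_clogs}} on the same
#'   table
#' @param genome_id a genome in the universe
#' @return named integer vector (core_genes, dispensable_genes, unique_genes)
#' @export
genome_profile <- function(table, classification, genome_id) {
  stopifnot(inherits(table, "clog_table"),
            inherits(classification, "clog_classification"))
  if (!genome_id %in% table$genomes)
    stop2("unknown genome id: ", genome_id)
  counts <- table$gene_counts[, genome_id]
  out <- vapply(c("core", "dispensable", "unique"), function(k)
    sum(counts[classification$class == k]), integer(1))
  names(out) <- c("core_genes", "dispensable_genes", "unique_genes")
  out
}

#' Unique-class CLOGs with two or more sequences
#'
#' CLOGs confined to one genome but holding several sequences are putative
#' paralog families.
#'
#' @inheritParams genome_profile
#' @return list with \code{count} and \code{clog_ids}
#' @export
multi_sequence_unique_clogs <- function(table, classification) {
  stopifnot(inherits(table, "clog_table"),
            inherits(classification, "clog_classification"))
  sizes <- rowSums(table$gene_counts)
  ids <- table$clog_ids[classification$class == "unique" & sizes >= 2L]
  list(count = length(ids), clog_ids = ids)
}

#' CLOG-sharing similarity between two strains
#'
#' Number of CLOGs containing both strains divided by the number of CLOGs
#' containing at least one of the two (the Jaccard index of the strains'
#' CLOG-presence sets); the companion distance is 1 - similarity.
#'
#' @param table a \code{clog_table}
#' @param x,y distinct genome ids in the universe
#' @return list with \code{similarity}, \code{distance}, \code{shared},
#'   \code{union}
#' @export
clog_similarity <- function(table, x, y) {
  stopifnot(inherits(table, "clog_table"))
  for (g in c(x, y)) if (!g %in% table$genomes)
    stop2("unknown genome id: ", g)
  if (identical(x, y))
    stop2("self-similarity is undefined; use clog_distance_matrix() for ",
          "matrices (diagonal 0 by convention)")
  p <- presence_matrix(table)
  shared <- sum(p[, x] & p[, y])
  un <- sum(p[, x] | p[, y])
  if (un == 0L)
    stop2("similarity undefined: neither ", x, " nor ", y,
          " occurs in any CLOG")
  list(similarity = shared / un, distance = 1 - shared / un,
       shared = shared, union = un)
}

#' Pairwise CLOG distance matrix over the genome universe
#'
#' @param table a \code{clog_table}
#' @return symmetric matrix of 1 - similarity with zero diagonal, labelled by
#'   genome id
#' @export
clog_distance_matrix <- function(table) {
  stopifnot(inherits(table, "clog_table"))
  g <- table$genomes
  p <- presence_matrix(table) * 1L
  shared <- crossprod(p)                       # G x G co-occurrence counts
  sizes <- diag(shared)
  un <- outer(sizes, sizes, "+") - shared
  if (any(un == 0 & upper.tri(un)))
    stop2("similarity undefined for genome pairs absent from every CLOG")
  d <- 1 - shared / un
  diag(d) <- 0
  dimnames(d) <- list(g, g)
  d
}

#' Confusion matrix between two classifications of the same CLOG set
#'
#' Convenience for method-comparison (e.g. two clustering pipelines run on
#' the same proteomes): cross-tabulates classes over the shared CLOG ids.
#'
#' @param a,b \code{clog_classification} objects
#' @return a contingency table (classes of \code{a} in rows)
#' @export
classification_confusion <- function(a, b) {
  stopifnot(inherits(a, "clog_classification"),
            inherits(b, "clog_classification"))
  shared <- intersect(names(a$class), names(b$class))
  table(a = a$class[shared], b = b$class[shared])
}
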