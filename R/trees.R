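# Neighbor-joining trees, patristic distances, AAI and alignment p-distances.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing Q(i, j) = (r - 2) d(i, j) - R_i - R_j (r = current number of
#' nodes, R = row sums), with branch lengths
#' v_i = d(i, j)/2 + (R_i - R_j) / (2(r - 2)) and v_j = d(i, j) - v_i.
#' A negative estimated length is clamped to zero and its deficit
#' transferred to the sister branch, preserving the pair's path length.
#' Ties in Q are broken deterministically by the (sorted) label pair. The
#' result is the standard unrooted binary topology with a trifurcating
#' central node.
#'
#' @param d symmetric labelled distance matrix (>= 3 labels, zero diagonal)
#' @return an \code{ape} \code{phylo} tree with branch lengths
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighbor_joining(d)   # leaf branches 1, 1, 3
#' @export
neighbor_joining <- function(d) {
  validate_distance_matrix(d)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 3) stop2("neighbor joining needs at least 3 labels")
  if (anyDuplicated(labels)) stop2("duplicate labels")

  fmt <- function(x) sprintf("%.15g", x)
  # newick fragment per active node; leaf names escaped if needed
  esc <- function(s) {
    if (grepl("[ ,:;()\\[\\]']", s))
      paste0("'", gsub("'", "''", s), "'") else s
  }
  node_str <- vapply(labels, esc, character(1))
  node_lab <- labels              # sort key for deterministic tie-breaks
  D <- unname(d)

  while (length(node_str) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)) & upper.tri(Q),
                  arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(node_lab[ij[1]], node_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    dij <- D[i, j]
    vi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- dij - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_str <- paste0("(", node_str[i], ":", fmt(vi), ",",
                      node_str[j], ":", fmt(vj), ")")
    new_lab <- min(node_lab[i], node_lab[j])
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_str <- c(node_str[keep], new_str)
    node_lab <- c(node_lab[keep], new_lab)
  }

  # final trifurcation by the three-taxon closed form
  dab <- D[1, 2]; dac <- D[1, 3]; dbc <- D[2, 3]
  v <- c((dab + dac - dbc) / 2,
         (dab + dbc - dac) / 2,
         (dac + dbc - dab) / 2)
  for (k in which(v < 0)) {         # clamp, deficit onto the longest sister
    others <- setdiff(1:3, k)
    tgt <- others[which.max(v[others])]
    v[tgt] <- v[tgt] + v[k]
    v[k] <- 0
  }
  v <- pmax(v, 0)
  nwk <- paste0("(", node_str[1], ":", fmt(v[1]), ",",
                node_str[2], ":", fmt(v[2]), ",",
                node_str[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = nwk)
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of
#' leaves.
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths
#' @return labelled symmetric matrix over the tree's tips
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop2("tree has missing branch lengths")
  n <- length(tree$tip.label)
  m <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

#' Patristic correlation between two trees
#'
#' Pearson correlation of the vectorized upper triangles of the two
#' patristic matrices, restricted to the shared leaves (1 = same branching
#' structure and proportional path lengths, -1 = anti-correlated).
#'
#' @param t1,t2 \code{phylo} trees with branch lengths sharing >= 3 leaves
#' @return correlation coefficient in [-1, 1]
#' @export
patristic_correlation <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 3)
    stop2("trees share fewer than 3 leaves")
  if (length(shared) < length(t1$tip.label)) t1 <- ape::keep.tip(t1, shared)
  if (length(shared) < length(t2$tip.label)) t2 <- ape::keep.tip(t2, shared)
  m1 <- patristic_matrix(t1)[shared, shared]
  m2 <- patristic_matrix(t2)[shared, shared]
  v1 <- upper_vec(m1); v2 <- upper_vec(m2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop2("patristic correlation undefined: zero variance in a tree's distances")
  stats::cor(v1, v2)
}

#' Single-copy core CLOGs
#'
#' Core CLOGs in which every genome contributes exactly one sequence; the
#' marker set used for AAI computation.
#'
#' @param table a \code{\link{clog_table}}
#' @param classification matching \code{\link{classify_clogs}} result
#' @return character vector of CLOG ids
#' @export
select_single_copy_core <- function(table, classification) {
  stopifnot(inherits(table, "clog_table"),
            inherits(classification, "clog_classification"))
  G <- length(table$genomes)
  is_core <- classification$class[table$clog_ids] == "core"
  single <- rowSums(table$gene_counts) == G        # core => all >= 1
  table$clog_ids[is_core & single]
}

#' Alignment scoring parameters
#'
#' @param substitution_matrix name of the substitution matrix (passed to
#'   \code{Biostrings::pairwiseAlignment})
#' @param gap_opening,gap_extension non-negative penalties
#' @export
aai_scoring <- function(substitution_matrix = "BLOSUM62",
                        gap_opening = 10, gap_extension = 0.5) {
  if (gap_opening < 0 || gap_extension < 0)
    stop2("gap penalties must be >= 0")
  list(substitution_matrix = substitution_matrix,
       gap_opening = gap_opening, gap_extension = gap_extension)
}

alignment_identity <- function(p, s, denominator, len_p, len_s) {
  cp <- strsplit(p, "")[[1]]; cs <- strsplit(s, "")[[1]]
  matches <- sum(cp == cs & cp != "-")
  cols <- switch(denominator,
                 columns = length(cp),
                 nongap = sum(cp != "-" & cs != "-"),
                 shortest = min(len_p, len_s))
  matches / cols
}

#' Average amino-acid identity (AAI) distance matrix
#'
#' For every genome pair and every selected single-copy CLOG, the two member
#' proteins are globally aligned (Needleman-Wunsch via
#' \code{Biostrings::pairwiseAlignment}) and the identity computed as
#' matches over alignment columns (denominator configurable). AAI(x, y) is
#' the mean identity over CLOGs; the returned matrix holds 1 - AAI.
#'
#' @param table a \code{\link{clog_table}}
#' @param clog_ids single-copy core CLOGs to use (non-empty)
#' @param sequences named character vector, gene_id -> amino-acid sequence,
#'   covering every member of the selected CLOGs
#' @param scoring an \code{\link{aai_scoring}} list
#' @param identity_denominator \code{"columns"} (all alignment columns,
#'   default), \code{"nongap"}, or \code{"shortest"}
#' @return list with \code{aai} (similarity matrix) and \code{distance}
#'   (1 - AAI, zero diagonal)
#' @export
aai_matrix <- function(table, clog_ids, sequences, scoring = aai_scoring(),
                       identity_denominator = c("columns", "nongap",
                                                "shortest")) {
  stopifnot(inherits(table, "clog_table"))
  identity_denominator <- match.arg(identity_denominator)
  if (!length(clog_ids)) stop2("empty CLOG selection")
  bad <- setdiff(clog_ids, table$clog_ids)
  if (length(bad)) stop2("unknown CLOG id: ", bad[1])
  m <- table$members[table$members$clog_id %in% clog_ids, , drop = FALSE]
  missing <- setdiff(m$gene_id, names(sequences))
  if (length(missing))
    stop2("missing sequence for gene(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  # gene of each genome per clog (single-copy assumed/validated)
  cnt <- table$gene_counts[clog_ids, , drop = FALSE]
  if (any(cnt != 1L))
    stop2("selected CLOGs must contain exactly one sequence per genome")
  g <- table$genomes
  gene_of <- matrix(NA_character_, length(clog_ids), length(g),
                    dimnames = list(clog_ids, g))
  for (r in seq_len(nrow(m)))
    gene_of[m$clog_id[r], m$genome_id[r]] <- m$gene_id[r]

  aai <- matrix(1, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)[-length(g)]) for (j in (i + 1):length(g)) {
    gx <- gene_of[, g[i]]; gy <- gene_of[, g[j]]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[gx]),
      Biostrings::AAStringSet(sequences[gy]),
      type = "global",
      substitutionMatrix = scoring$substitution_matrix,
      gapOpening = scoring$gap_opening,
      gapExtension = scoring$gap_extension)
    ps <- as.character(Biostrings::alignedPattern(aln))
    ss <- as.character(Biostrings::alignedSubject(aln))
    ids <- vapply(seq_along(ps), function(k)
      alignment_identity(ps[k], ss[k], identity_denominator,
                         nchar(sequences[gx[k]]), nchar(sequences[gy[k]])),
      numeric(1))
    aai[i, j] <- aai[j, i] <- mean(ids)
  }
  dist <- 1 - aai
  diag(dist) <- 0
  list(aai = aai, distance = dist)
}

#' p-distance matrix from a multiple sequence alignment
#'
#' Pairwise proportion of mismatching columns, skipping columns where
#' either sequence has a gap ("-" or ".").
#'
#' @param alignment named character vector of equal-length aligned rows, or
#'   anything coercible via \code{as.character} (e.g. a
#'   \code{Biostrings::DNAStringSet})
#' @return labelled symmetric distance matrix
#' @export
msa_p_distance <- function(alignment) {
  aln <- if (is.character(alignment)) alignment else as.character(alignment)
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop2("alignment rows need unique names")
  L <- unique(nchar(aln))
  if (length(L) != 1)
    stop2("ragged alignment: rows have different lengths")
  chars <- do.call(rbind, strsplit(aln, ""))
  gap <- chars == "-" | chars == "."
  n <- length(aln)
  if (n < 2) stop2("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    use <- !gap[i, ] & !gap[j, ]
    if (!any(use))
      stop2("no comparable columns for pair (", names(aln)[i], ", ",
            names(aln)[j], ")")
    d[i, j] <- d[j, i] <- sum(chars[i, use] != chars[j, use]) / sum(use)
  }
  d
}
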