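# Feature-specific CLOG mining and the outgroup specificity filter.
#
# A feature strain set partitions the universe into strains positive for a
# phenotype (members), negative (excluded) and unknown. Candidate CLOGs are
# those whose member genomes sit entirely inside the positive set; exact
# candidates additionally cover every positive strain. Candidates become
# "signature genes" when an outgroup homology search yields no qualifying
# hit (>= 80% bait coverage and e-value <= 1e-10 by default).

#' Feature strain set
#'
#' @param feature_name label of the phenotype
#' @param members genome ids positive for the feature
#' @param excluded genome ids negative for the feature
#' @param unknown genome ids with no information (treated as non-members)
#' @return object of class \code{feature_strain_set}
#' @export
feature_strain_set <- function(feature_name, members, excluded = character(),
                               unknown = character()) {
  members <- as.character(members); excluded <- as.character(excluded)
  unknown <- as.character(unknown)
  all3 <- c(members, excluded, unknown)
  if (anyDuplicated(all3))
    stop2("members/excluded/unknown must be disjoint")
  structure(list(feature_name = feature_name, members = members,
                 excluded = excluded, unknown = unknown),
            class = "feature_strain_set")
}

#' Read a feature strain set from file
#'
#' One genome id per line followed by its status: \code{+} (member),
#' \code{-} (excluded) or \code{u} (unknown), whitespace-separated.
#'
#' @param path file path
#' @param feature_name label (defaults to the file name)
#' @export
read_feature_strain_set <- function(path, feature_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  if (any(lengths(toks) != 2))
    stop2("each line must be: genome_id status(+/-/u)")
  ids <- vapply(toks, `[`, character(1), 1)
  st <- vapply(toks, `[`, character(1), 2)
  if (any(!st %in% c("+", "-", "u")))
    stop2("status must be one of +, -, u")
  feature_strain_set(feature_name,
                     members = ids[st == "+"],
                     excluded = ids[st == "-"],
                     unknown = ids[st == "u"])
}

#' CLOGs exactly matching a feature strain set
#'
#' CLOGs whose member-genome set equals the feature's positive strains
#' exactly: every positive strain contributes at least one sequence and no
#' other strain contributes any.
#'
#' @param table a \code{\link{clog_table}}
#' @param fs a \code{\link{feature_strain_set}} with >= 1 member
#' @return character vector of CLOG ids
#' @export
exact_feature_clogs <- function(table, fs) {
  stopifnot(inherits(table, "clog_table"),
            inherits(fs, "feature_strain_set"))
  if (!length(fs$members)) stop2("feature set has no member strains")
  bad <- setdiff(fs$members, table$genomes)
  if (length(bad)) stop2("members outside universe: ", paste(bad, collapse = ", "))
  p <- presence_matrix(table)
  inset <- table$genomes %in% fs$members
  hit <- rowSums(p[, inset, drop = FALSE]) == length(fs$members) &
    rowSums(p[, !inset, drop = FALSE]) == 0L
  table$clog_ids[hit]
}

#' Feature-specific CLOGs at relaxed support
#'
#' CLOGs whose member genomes are a subset of the feature's positive
#' strains, bucketed by how many positive strains they cover (support).
#' All buckets with support >= \code{min_support} are returned; the union
#' of their member gene ids is the relaxed core set of the feature.
#'
#' @inheritParams exact_feature_clogs
#' @param min_support minimal number of positive strains covered
#'   (1..|members|)
#' @return list with \code{buckets} (named list support level ->
#'   CLOG ids, highest support first), \code{clog_ids} (all qualifying) and
#'   \code{genes} (their member gene ids)
#' @export
relaxed_feature_clogs <- function(table, fs, min_support) {
  stopifnot(inherits(table, "clog_table"),
            inherits(fs, "feature_strain_set"))
  k <- min_support
  if (k < 1 || k > length(fs$members))
    stop2("min_support out of range 1..", length(fs$members))
  p <- presence_matrix(table)
  inset <- table$genomes %in% fs$members
  support <- rowSums(p[, inset, drop = FALSE])
  exclusive <- rowSums(p[, !inset, drop = FALSE]) == 0L
  levels_ <- seq(length(fs$members), k)
  buckets <- lapply(levels_, function(s)
    table$clog_ids[exclusive & support == s])
  names(buckets) <- as.character(levels_)
  ids <- unlist(buckets, use.names = FALSE)
  genes <- table$members$gene_id[table$members$clog_id %in% ids]
  list(buckets = buckets, clog_ids = ids, genes = genes)
}

#' Marker CLOG presence profile across strain classes
#'
#' For a curated set of marker CLOGs (e.g. known heterocyst-differentiation
#' genes), counts per genome how many marker CLOGs contain it, summarizes
#' by phenotype class and flags markers missing from any positive strain.
#'
#' @param table a \code{\link{clog_table}}
#' @param marker_clogs CLOG ids present in the table
#' @param classes named character vector genome_id -> one of
#'   \code{"positive"}, \code{"negative"}, \code{"unknown"}
#' @return list with \code{per_genome} (data.frame genome_id, class,
#'   n_markers), \code{class_summary} (mean count per class) and
#'   \code{incomplete_markers} (markers absent from >= 1 positive genome,
#'   with the missing genomes)
#' @export
marker_profile <- function(table, marker_clogs, classes) {
  stopifnot(inherits(table, "clog_table"))
  bad <- setdiff(marker_clogs, table$clog_ids)
  if (length(bad)) stop2("unknown CLOG id: ", bad[1])
  cls <- classes[table$genomes]
  if (anyNA(cls)) stop2("classes must cover every genome in the universe")
  if (any(!cls %in% c("positive", "negative", "unknown")))
    stop2("classes must be positive/negative/unknown")
  p <- presence_matrix(table)[marker_clogs, , drop = FALSE]
  n_markers <- colSums(p)
  per_genome <- data.frame(genome_id = table$genomes, class = unname(cls),
                           n_markers = unname(n_markers),
                           stringsAsFactors = FALSE)
  class_summary <- tapply(per_genome$n_markers, per_genome$class, mean)
  pos <- table$genomes[cls == "positive"]
  incomplete <- lapply(marker_clogs, function(cid) {
    miss <- pos[!p[cid, pos]]
    if (length(miss)) miss else NULL
  })
  names(incomplete) <- marker_clogs
  incomplete <- incomplete[!vapply(incomplete, is.null, logical(1))]
  list(per_genome = per_genome, class_summary = class_summary,
       incomplete_markers = incomplete)
}

#' Outgroup specificity filter for signature candidates
#'
#' A homology hit qualifies when the bait (query) coverage is at least
#' \code{min_coverage} and the e-value at most \code{max_evalue} (both
#' inclusive). A query is a signature candidate when no qualifying hit
#' exists in any outgroup taxon. Per query x taxon, both the number of
#' qualifying hit rows and the number of distinct subject sequences are
#' reported.
#'
#' @param hits data.frame of hit records (see \code{\link{read_hit_table}})
#' @param min_coverage minimal bait coverage, fraction (default 0.80)
#' @param max_evalue maximal e-value (default 1.0e-10)
#' @param queries optional character vector of query ids to report even if
#'   they have no hits at all (these are signatures by definition)
#' @return list with \code{qualifying} (the qualifying hit rows),
#'   \code{is_signature} (named logical per query) and \code{taxon_counts}
#'   (data.frame query_id, subject_taxon, n_hits, n_subjects)
#' @export
specificity_filter <- function(hits, min_coverage = 0.80,
                               max_evalue = 1.0e-10, queries = NULL) {
  if (min_coverage < 0 || min_coverage > 1)
    stop2("min_coverage must be in [0,1]")
  if (max_evalue < 0) stop2("max_evalue must be >= 0")
  ok <- hits$query_coverage >= min_coverage & hits$e_value <= max_evalue
  qual <- hits[ok, , drop = FALSE]
  all_q <- unique(c(hits$query_id, queries))
  is_signature <- !(all_q %in% qual$query_id)
  names(is_signature) <- all_q
  if (nrow(qual)) {
    key <- interaction(qual$query_id, qual$subject_taxon, drop = TRUE)
    taxon_counts <- do.call(rbind, lapply(split(qual, key), function(d)
      data.frame(query_id = d$query_id[1], subject_taxon = d$subject_taxon[1],
                 n_hits = nrow(d), n_subjects = length(unique(d$subject_id)),
                 stringsAsFactors = FALSE)))
    rownames(taxon_counts) <- NULL
  } else {
    taxon_counts <- data.frame(query_id = character(),
                               subject_taxon = character(),
                               n_hits = integer(), n_subjects = integer(),
                               stringsAsFactors = FALSE)
  }
  list(qualifying = qual, is_signature = is_signature,
       taxon_counts = taxon_counts)
}
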