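# Consensus categorization of beta-barrel outer-membrane proteins.
#
# Four criteria per protein. Major: (1) TMBp consensus — called beta-barrel
# by more than one sequence-based predictor; (2) pHMM — at least one
# beta-barrel family profile hit. Minor: (3) Pfam potential — an uncovered
# stretch longer than 79 residues remains after masking non-barrel Pfam
# domains; (4) CLOG detected — the protein passes both majors and more than
# 50% of all sequences of its CLOG do too. Categories: (a) both majors +
# both minors; (b) both majors + exactly one minor; (c) both majors only,
# retained after structural confirmation; (d) everything else.

#' Beta-barrel evidence table
#'
#' One row per protein with list-columns holding the per-protein evidence.
#'
#' @param protein_id,genome_id character vectors
#' @param length integer residue lengths (>= 1)
#' @param predictor_votes list of character vectors (predictor names that
#'   called beta-barrel)
#' @param phmm_hits list of data.frames with columns \code{family},
#'   \code{start}, \code{end}, \code{evalue}, \code{bits} (0-row allowed)
#' @param pfam_intervals list of 2-column matrices (start, end; 1-based
#'   inclusive) of non-barrel Pfam domain coverage
#' @param clog_id character (NA = not clustered)
#' @param structural_override logical (structure-level confirmation for
#'   category-c retention)
#' @return object of class \code{barrel_evidence} (a data.frame)
#' @export
barrel_evidence <- function(protein_id, genome_id, length, predictor_votes,
                            phmm_hits, pfam_intervals, clog_id,
                            structural_override) {
  n <- length(protein_id)
  stopifnot(length(genome_id) == n, length(length) == n,
            length(predictor_votes) == n, length(phmm_hits) == n,
            length(pfam_intervals) == n, length(clog_id) == n,
            length(structural_override) == n)
  if (anyDuplicated(protein_id)) stop2("duplicate protein ids")
  if (any(length < 1)) stop2("protein length must be >= 1")
  for (i in seq_len(n)) {
    iv <- pfam_intervals[[i]]
    if (!is.null(iv) && nrow(iv)) {
      if (any(iv[, 1] > iv[, 2]))
        stop2(protein_id[i], ": interval start > end")
      if (any(iv[, 1] < 1 | iv[, 2] > length[i]))
        stop2(protein_id[i], ": interval outside [1, length]")
    }
  }
  ev <- data.frame(protein_id = as.character(protein_id),
                   genome_id = as.character(genome_id),
                   length = as.integer(length),
                   clog_id = as.character(clog_id),
                   structural_override = as.logical(structural_override),
                   stringsAsFactors = FALSE)
  ev$predictor_votes <- predictor_votes
  ev$phmm_hits <- phmm_hits
  ev$pfam_intervals <- pfam_intervals
  class(ev) <- c("barrel_evidence", "data.frame")
  ev
}

#' TMBp predictor consensus (major criterion 1)
#'
#' TRUE when more than one predictor on the roster called the protein a
#' beta-barrel (a single vote is insufficient).
#'
#' @param votes character vector of predictor names that voted beta-barrel
#' @param roster declared predictor roster
#' @export
tmbp_consensus <- function(votes,
                           roster = c("BOMP", "KNN", "TMBetaDisc", "HHensemble")) {
  bad <- setdiff(votes, roster)
  if (length(bad))
    stop2("vote from predictor not on the roster: ", paste(bad, collapse = ", "))
  length(unique(votes)) >= 2L
}

#' pHMM probability (major criterion 2) and family label
#'
#' TRUE when at least one beta-barrel family profile hit exists. The family
#' label is taken from the best hit: lowest e-value, ties broken by higher
#' bit score, then alphabetically by family name.
#'
#' @param hits data.frame with columns family, start, end, evalue, bits
#' @return list with \code{probable} and \code{family} (NA when no hit)
#' @export
phmm_probable <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(probable = FALSE, family = NA_character_))
  ord <- order(hits$evalue, -hits$bits, hits$family)
  list(probable = TRUE, family = hits$family[ord[1]])
}

# merge 1-based inclusive intervals; returns matrix with start <= end,
# sorted, non-overlapping
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(numeric(0), 0, 2))
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv[r, 1] <= out[last, 2] + 1) {
      out[last, 2] <- max(out[last, 2], iv[r, 2])
    } else {
      out <- rbind(out, iv[r, , drop = FALSE])
    }
  }
  out
}

#' Pfam potential (minor criterion 1)
#'
#' TRUE when, after masking the residues covered by non-barrel Pfam
#' domains, an uncovered stretch longer than 79 residues (i.e. >= 80)
#' remains.
#'
#' @param length protein length in residues
#' @param intervals 2-column matrix of covered [start, end] intervals
#'   (1-based, inclusive), possibly 0-row
#' @export
pfam_potential <- function(length, intervals) {
  if (length < 1) stop2("length must be >= 1")
  m <- merge_intervals(intervals)
  if (!nrow(m)) return(length >= 80)
  if (any(m[, 1] < 1 | m[, 2] > length))
    stop2("interval outside [1, length]")
  gaps <- c(m[1, 1] - 1,                                   # before first
            if (nrow(m) > 1) m[-1, 1] - m[-nrow(m), 2] - 1, # between
            length - m[nrow(m), 2])                        # after last
  max(gaps) >= 80
}

#' CLOG detection vote (minor criterion 2)
#'
#' A CLOG passes when more than 50% of \emph{all} its member sequences pass
#' both major criteria; members without an evidence row count as
#' non-passing. A protein's flag is TRUE only when its CLOG passes and the
#' protein itself passes both majors. Unclustered proteins are FALSE.
#'
#' @param table a \code{\link{clog_table}} (the denominator source)
#' @param protein_id character vector
#' @param clog_id character vector (NA = unclustered)
#' @param major_pass logical vector (tmbp AND phmm per protein)
#' @return list with \code{per_protein} (named logical) and
#'   \code{per_clog} (named logical over the CLOGs seen)
#' @export
clog_detected <- function(table, protein_id, clog_id, major_pass) {
  stopifnot(inherits(table, "clog_table"))
  n <- length(protein_id)
  stopifnot(length(clog_id) == n, length(major_pass) == n)
  seen <- unique(clog_id[!is.na(clog_id)])
  bad <- setdiff(seen, table$clog_ids)
  if (length(bad))
    stop2("evidence references CLOG absent from table: ", bad[1])
  sizes <- rowSums(table$gene_counts)
  per_clog <- vapply(seen, function(cid) {
    passing <- sum(major_pass[!is.na(clog_id) & clog_id == cid])
    passing / sizes[[cid]] > 0.5
  }, logical(1))
  per_protein <- ifelse(is.na(clog_id), FALSE,
                        major_pass & per_clog[clog_id])
  per_protein[is.na(per_protein)] <- FALSE
  names(per_protein) <- protein_id
  list(per_protein = per_protein, per_clog = per_clog)
}

category_from_flags <- function(tmbp, phmm, pfam, clog, override) {
  if (!(tmbp && phmm)) return("d")
  m <- sum(pfam, clog)
  if (m == 2) "a" else if (m == 1) "b" else if (override) "c" else "d"
}

#' Categorize proteins by the consensus decision table
#'
#' Computes the four criteria for every protein in an evidence table and
#' assigns categories (a)-(d).
#'
#' @param evidence a \code{\link{barrel_evidence}} table
#' @param table optional \code{\link{clog_table}} for the CLOG vote; when
#'   omitted, \code{clog_detected} is FALSE for everyone
#' @param roster predictor roster for vote validation
#' @return data.frame of class \code{barrel_calls}: protein_id, genome_id,
#'   tmbp_probable, phmm_probable, pfam_potential, clog_detected, category,
#'   family, clog_id
#' @export
categorize_barrels <- function(evidence, table = NULL,
                               roster = c("BOMP", "KNN", "TMBetaDisc",
                                          "HHensemble")) {
  stopifnot(inherits(evidence, "barrel_evidence"))
  n <- nrow(evidence)
  tmbp <- vapply(evidence$predictor_votes, tmbp_consensus, logical(1),
                 roster = roster)
  ph <- lapply(evidence$phmm_hits, phmm_probable)
  phmm <- vapply(ph, `[[`, logical(1), "probable")
  family <- vapply(ph, `[[`, character(1), "family")
  pfam <- vapply(seq_len(n), function(i)
    pfam_potential(evidence$length[i], evidence$pfam_intervals[[i]]),
    logical(1))
  majors <- tmbp & phmm
  if (!is.null(table)) {
    cd <- clog_detected(table, evidence$protein_id, evidence$clog_id, majors)
    clog_flag <- unname(cd$per_protein)
  } else {
    clog_flag <- rep(FALSE, n)
  }
  category <- vapply(seq_len(n), function(i)
    category_from_flags(tmbp[i], phmm[i], pfam[i], clog_flag[i],
                        evidence$structural_override[i]), character(1))
  out <- data.frame(protein_id = evidence$protein_id,
                    genome_id = evidence$genome_id,
                    tmbp_probable = tmbp, phmm_probable = phmm,
                    pfam_potential = pfam, clog_detected = clog_flag,
                    category = factor(category, levels = c("a", "b", "c", "d")),
                    family = family,
                    clog_id = evidence$clog_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("barrel_calls", "data.frame")
  out
}

#' Per-family summary of beta-barrel calls
#'
#' For each pHMM family label among category a/b/c calls: the number of
#' distinct strains, of distinct taxonomic orders (via the registry) and of
#' sequences, plus a family x CLOG cross-tabulation.
#'
#' @param calls a \code{barrel_calls} data.frame
#' @param registry a \code{\link{genome_registry}} covering the call genomes
#' @param table optional \code{\link{clog_table}} (for the cross-tab)
#' @return list with \code{families} (data.frame family, n_strains,
#'   n_orders, n_sequences) and \code{clog_crosstab}
#' @export
family_summary <- function(calls, registry, table = NULL) {
  stopifnot(inherits(calls, "barrel_calls"),
            inherits(registry, "genome_registry"))
  keep <- calls$category %in% c("a", "b", "c") & !is.na(calls$family)
  k <- calls[keep, , drop = FALSE]
  order_of <- stats::setNames(registry$genomes$order,
                              registry$genomes$genome_id)
  if (any(!k$genome_id %in% names(order_of)))
    stop2("call genomes missing from registry")
  fam_split <- split(k, k$family)
  families <- do.call(rbind, lapply(fam_split, function(d)
    data.frame(family = d$family[1],
               n_strains = length(unique(d$genome_id)),
               n_orders = length(unique(order_of[d$genome_id])),
               n_sequences = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(families) <- NULL
  crosstab <- if (!is.null(table))
    table(family = k$family, clog = ifelse(is.na(k$clog_id), "<none>",
                                           k$clog_id))
  else NULL
  list(families = families, clog_crosstab = crosstab)
}

#' Read / write a beta-barrel evidence TSV
#'
#' Columns: protein_id, genome_id, length, votes (";"-joined predictor
#' names, empty allowed), phmm (";"-joined \code{family:start-end:evalue:bits}
#' tokens), pfam (";"-joined \code{start-end} tokens), clog_id (empty =
#' unclustered), override (0/1).
#'
#' @param path file path
#' @export
read_barrel_evidence <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("protein_id", "genome_id", "length", "votes", "phmm", "pfam",
            "clog_id", "override")
  if (!all(need %in% names(df)))
    stop2("evidence file needs columns: ", paste(need, collapse = ", "))
  split_semi <- function(s) if (nzchar(s)) strsplit(s, ";", fixed = TRUE)[[1]]
                            else character()
  votes <- lapply(df$votes, split_semi)
  phmm <- lapply(df$phmm, function(s) {
    toks <- split_semi(s)
    if (!length(toks))
      return(data.frame(family = character(), start = integer(),
                        end = integer(), evalue = numeric(), bits = numeric()))
    parts <- strsplit(toks, ":", fixed = TRUE)
    if (any(lengths(parts) != 4))
      stop2("malformed pHMM token (family:start-end:evalue:bits): ", s)
    se <- strsplit(vapply(parts, `[`, character(1), 2), "-", fixed = TRUE)
    data.frame(family = vapply(parts, `[`, character(1), 1),
               start = as.integer(vapply(se, `[`, character(1), 1)),
               end = as.integer(vapply(se, `[`, character(1), 2)),
               evalue = as.numeric(vapply(parts, `[`, character(1), 3)),
               bits = as.numeric(vapply(parts, `[`, character(1), 4)),
               stringsAsFactors = FALSE)
  })
  pfam <- lapply(df$pfam, function(s) {
    toks <- split_semi(s)
    if (!length(toks)) return(matrix(numeric(0), 0, 2))
    se <- strsplit(toks, "-", fixed = TRUE)
    if (any(lengths(se) != 2)) stop2("malformed Pfam interval: ", s)
    cbind(as.numeric(vapply(se, `[`, character(1), 1)),
          as.numeric(vapply(se, `[`, character(1), 2)))
  })
  barrel_evidence(df$protein_id, df$genome_id, as.integer(df$length),
                  votes, phmm, pfam,
                  ifelse(nzchar(df$clog_id), df$clog_id, NA_character_),
                  df$override == "1")
}

#' @rdname read_barrel_evidence
#' @param evidence a \code{\link{barrel_evidence}} table
#' @export
write_barrel_evidence <- function(evidence, path) {
  stopifnot(inherits(evidence, "barrel_evidence"))
  join <- function(x) paste(x, collapse = ";")
  out <- data.frame(
    protein_id = evidence$protein_id,
    genome_id = evidence$genome_id,
    length = evidence$length,
    votes = vapply(evidence$predictor_votes, join, character(1)),
    phmm = vapply(evidence$phmm_hits, function(h) {
      if (!nrow(h)) return("")
      join(sprintf("%s:%d-%d:%g:%g", h$family, h$start, h$end, h$evalue,
                   h$bits))
    }, character(1)),
    pfam = vapply(evidence$pfam_intervals, function(iv) {
      if (!nrow(iv)) return("")
      join(sprintf("%d-%d", as.integer(iv[, 1]), as.integer(iv[, 2])))
    }, character(1)),
    clog_id = ifelse(is.na(evidence$clog_id), "", evidence$clog_id),
    override = as.integer(evidence$structural_override),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
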