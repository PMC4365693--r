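# Readers/writers for the external table formats and the sequence QC rules
# applied before clustering. All identifiers are case-sensitive.

#' Genome registry
#'
#' The strain universe: genome ids with species/order labels and optional
#' genome statistics. Every genome referenced by any other structure must
#' exist here.
#'
#' @param genomes data.frame with columns \code{genome_id}, \code{species},
#'   \code{order} (character) and optionally \code{genome_size_mb} (positive
#'   numeric), \code{orf_count} (non-negative integer).
#' @return object of class \code{genome_registry}
#' @export
genome_registry <- function(genomes) {
  stopifnot(is.data.frame(genomes))
  need <- c("genome_id", "species", "order")
  if (!all(need %in% names(genomes)))
    stop2("registry needs columns: ", paste(need, collapse = ", "))
  genomes$genome_id <- as.character(genomes$genome_id)
  if (any(genomes$genome_id == "") || anyDuplicated(genomes$genome_id))
    stop2("genome ids must be unique and non-empty")
  if (!is.null(genomes$genome_size_mb) &&
      any(genomes$genome_size_mb <= 0, na.rm = TRUE))
    stop2("genome_size_mb must be positive")
  if (!is.null(genomes$orf_count) && any(genomes$orf_count < 0, na.rm = TRUE))
    stop2("orf_count must be non-negative")
  structure(list(genomes = genomes), class = "genome_registry")
}

#' @rdname genome_registry
#' @param path TSV file with a header naming at least genome_id, species,
#'   order
#' @export
read_genome_registry <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genome_registry(df)
}

#' @rdname genome_registry
#' @param registry a \code{genome_registry}
#' @export
write_genome_registry <- function(registry, path) {
  stopifnot(inherits(registry, "genome_registry"))
  utils::write.table(registry$genomes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.genome_registry <- function(x, ...) {
  cat("Genome registry:", nrow(x$genomes), "genomes,",
      length(unique(x$genomes$order)), "orders\n")
  invisible(x)
}

#' Read a CLOG table from file
#'
#' Two dialects are supported. \code{"orthomcl_groups"}: one cluster per
#' line, \code{"clog_id: genome|gene genome|gene ..."}; the member token is
#' split on the \emph{first} \code{"|"}, so gene ids may themselves contain
#' \code{"|"}. \code{"tsv"}: a headered three-column file (clog_id,
#' genome_id, gene_id), one row per member.
#'
#' @param path input file
#' @param format \code{"orthomcl_groups"} or \code{"tsv"}
#' @param genomes optional genome universe (defaults to genomes observed)
#' @return a \code{\link{clog_table}}
#' @export
read_clog_table <- function(path, format = c("orthomcl_groups", "tsv"),
                            genomes = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    return(clog_table(df, genomes = genomes))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(clog_table(data.frame(clog_id = character(),
                                 genome_id = character(),
                                 gene_id = character()), genomes = genomes))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0)
      stop2("line ", i, ": missing 'clog_id:' prefix")
    cid <- trimws(substr(ln, 1L, colon - 1L))
    toks <- strsplit(trimws(substr(ln, colon + 1L, nchar(ln))), "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (cid == "" || !length(toks))
      stop2("line ", i, ": cluster id or members missing")
    bar <- regexpr("|", toks, fixed = TRUE)
    if (any(bar < 1))
      stop2("line ", i, ": malformed member token (expected genome|gene): ",
            toks[which(bar < 1)[1]])
    rows[[i]] <- data.frame(
      clog_id = cid,
      genome_id = substr(toks, 1L, bar - 1L),
      gene_id = substr(toks, bar + 1L, nchar(toks)),
      stringsAsFactors = FALSE)
  }
  clog_table(do.call(rbind, rows), genomes = genomes)
}

#' Write a CLOG table
#'
#' Members are emitted in canonical order (clog id, genome id, gene id) so
#' that write-then-read is the identity up to member order.
#'
#' @param table a \code{\link{clog_table}}
#' @param path output file
#' @inheritParams read_clog_table
#' @export
write_clog_table <- function(table, path,
                             format = c("orthomcl_groups", "tsv")) {
  stopifnot(inherits(table, "clog_table"))
  format <- match.arg(format)
  m <- table$members
  m <- m[order(m$clog_id, m$genome_id, m$gene_id), , drop = FALSE]
  if (format == "tsv") {
    utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(split(m, factor(m$clog_id, levels = unique(m$clog_id))),
                    function(d) paste0(d$clog_id[1], ": ",
                                       paste(d$genome_id, d$gene_id,
                                             sep = "|", collapse = " ")),
                    character(1))
    writeLines(unname(lines), path)
  }
  invisible(path)
}

#' Protein sequence quality control
#'
#' Flags poor-quality sequences before clustering: shorter than 10 residues,
#' or with a stop-codon ("*") frequency above 20\% of the sequence length.
#' Every character counts toward the length; ambiguity codes are ordinary
#' residues.
#'
#' @param sequence non-empty amino-acid string (may contain "*")
#' @return one of \code{"pass"}, \code{"fail_short"}, \code{"fail_stops"}
#' @examples
#' qc_protein("MKVLITDEQ")      # 9 residues -> fail_short
#' qc_protein("MKVLITDEQL")     # 10 residues -> pass
#' @export
qc_protein <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0L) stop2("sequence must be non-empty")
  if (n < 10L) return("fail_short")
  stops <- nchar(sequence) - nchar(gsub("*", "", sequence, fixed = TRUE))
  if (stops / n > 0.20) "fail_stops" else "pass"
}

#' CDS/protein length pairing check
#'
#' A coding sequence must stand in a 3:1 length relation to its protein;
#' both the stop-codon-included (3(L+1) nucleotides) and excluded (3L)
#' encodings pass.
#'
#' @param cds_length CDS length in nucleotides (positive integer)
#' @param protein_length protein length in residues (positive integer)
#' @return \code{"pass"} or \code{"fail"}
#' @export
qc_cds_pairing <- function(cds_length, protein_length) {
  if (any(c(cds_length, protein_length) <= 0) ||
      any(c(cds_length, protein_length) != round(c(cds_length, protein_length))))
    stop2("lengths must be positive integers")
  if (cds_length == 3 * protein_length ||
      cds_length == 3 * (protein_length + 1)) "pass" else "fail"
}

#' Read a tabular homology hit file
#'
#' Tab-separated rows in a BLAST outfmt-6-like layout; the column map names
#' which (1-based) columns hold query id, subject id, subject taxon, query
#' coverage and e-value. Coverage given in percent (the common dialect) is
#' normalized to a fraction.
#'
#' @param path input file
#' @param columns named integer vector with entries \code{query},
#'   \code{subject}, \code{taxon}, \code{coverage}, \code{evalue}
#' @param coverage_unit \code{"percent"} (default, divided by 100) or
#'   \code{"fraction"}
#' @return data.frame of hit records: \code{query_id}, \code{subject_id},
#'   \code{subject_taxon}, \code{query_coverage} (fraction), \code{e_value}
#' @export
read_hit_table <- function(path,
                           columns = c(query = 1L, subject = 2L, taxon = 3L,
                                       coverage = 4L, evalue = 5L),
                           coverage_unit = c("percent", "fraction")) {
  coverage_unit <- match.arg(coverage_unit)
  need <- c("query", "subject", "taxon", "coverage", "evalue")
  if (!all(need %in% names(columns)))
    stop2("column map needs entries: ", paste(need, collapse = ", "))
  empty <- data.frame(query_id = character(), subject_id = character(),
                      subject_taxon = character(), query_coverage = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (!any(nzchar(readLines(path, n = 10L)))) return(empty)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) return(empty)
  if (max(columns) > ncol(raw))
    stop2("column map references column ", max(columns), " but file has ",
          ncol(raw))
  cov <- suppressWarnings(as.numeric(raw[[columns[["coverage"]]]]))
  ev <- suppressWarnings(as.numeric(raw[[columns[["evalue"]]]]))
  if (anyNA(ev))
    stop2("unparsable e-value at row ", which(is.na(ev))[1])
  if (anyNA(cov))
    stop2("unparsable coverage at row ", which(is.na(cov))[1])
  if (any(ev < 0))
    stop2("negative e-value at row ", which(ev < 0)[1])
  if (coverage_unit == "percent") {
    if (any(cov < 0 | cov > 100))
      stop2("coverage outside [0,100] at row ", which(cov < 0 | cov > 100)[1])
    cov <- cov / 100
  } else if (any(cov < 0 | cov > 1)) {
    stop2("coverage outside [0,1] at row ", which(cov < 0 | cov > 1)[1])
  }
  data.frame(query_id = raw[[columns[["query"]]]],
             subject_id = raw[[columns[["subject"]]]],
             subject_taxon = raw[[columns[["taxon"]]]],
             query_coverage = cov,
             e_value = ev,
             stringsAsFactors = FALSE)
}

#' Read / write a square labelled distance matrix
#'
#' Square TSV with a header row and a leading label column; labels must
#' agree between rows and columns.
#'
#' @param path file path
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m)))
    stop2("row and column labels disagree")
  validate_distance_matrix(m)
  m
}

#' @rdname read_distance_matrix
#' @param d symmetric labelled matrix
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop2("distance matrix must be square")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    stop2("distance matrix needs unique labels")
  if (any(!is.finite(d)))
    stop2("distance matrix has non-finite entries")
  if (any(d < 0))
    stop2("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-8)
    stop2("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12))
    stop2("distance matrix diagonal must be zero")
  invisible(d)
}
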