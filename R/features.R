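# Phenotype feature model and the Tanimoto-like similarity index.
#
# Each feature (habitat, cell shape, nitrogen fixation, ...) has an ordered
# set of subcategories; a strain's value is a bit string over them (1 =
# subcategory present, 0 = absent) or the sentinel "unknown". Comparing two
# strains, a feature unknown in both is skipped; a feature known in exactly
# one adds 0.5 to the denominator; a feature known in both adds the popcount
# of the bitwise AND to the numerator and of the OR to the denominator.
# Similarity = numerator/denominator, distance = 1 - similarity.

#' Phenotype feature table
#'
#' @param features named list: feature name -> character vector of ordered
#'   subcategory names
#' @param values character matrix (genomes x features, dimnames required):
#'   each entry a bit string ("0"/"1" characters, length = subcategory
#'   count) or \code{NA} for unknown. A known all-zero string means the
#'   feature was assessed and every subcategory is absent.
#' @return object of class \code{feature_table}
#' @export
feature_table <- function(features, values) {
  stopifnot(is.list(features), !is.null(names(features)),
            is.matrix(values), is.character(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("'values' needs genome row names and feature column names")
  if (!identical(colnames(values), names(features)))
    stop2("value columns must match feature names (same order)")
  for (f in names(features)) {
    v <- values[, f]
    known <- !is.na(v)
    if (any(nchar(v[known]) != length(features[[f]])))
      stop2("feature '", f, "': bit string length must equal its ",
            length(features[[f]]), " subcategories")
    if (any(grepl("[^01]", v[known])))
      stop2("feature '", f, "': bit strings may contain only 0/1")
  }
  structure(list(features = features, values = values),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$values), "genomes x", ncol(x$values),
      "features;", sum(is.na(x$values)), "unknown entries\n")
  invisible(x)
}

bits <- function(s) as.integer(strsplit(s, "")[[1]])

#' Tanimoto-like similarity between two strains
#'
#' Implements the unknown-aware bit-string index: per feature, unknown in
#' both strains -> skipped; unknown in exactly one -> denominator + 0.5;
#' known in both -> numerator + popcount(AND), denominator + popcount(OR).
#'
#' @param ft a \code{\link{feature_table}}
#' @param x,y genome ids present in the table
#' @return object of class \code{tanimoto_similarity}: \code{numerator},
#'   \code{denominator}, \code{similarity}, \code{distance},
#'   \code{features_used}, \code{features_skipped}
#' @examples
#' ft <- feature_table(
#'   list(habitat = c("sea", "fresh")),
#'   matrix(c("10", "11"), 2, 1, dimnames = list(c("A", "B"), "habitat")))
#' tanimoto_similarity(ft, "A", "B")$similarity   # 1/2
#' @export
tanimoto_similarity <- function(ft, x, y) {
  stopifnot(inherits(ft, "feature_table"))
  for (g in c(x, y)) if (!g %in% rownames(ft$values))
    stop2("genome not in feature table: ", g)
  num <- 0; den <- 0; used <- character(); skipped <- character()
  for (f in colnames(ft$values)) {
    vx <- ft$values[x, f]; vy <- ft$values[y, f]
    if (is.na(vx) && is.na(vy)) {
      skipped <- c(skipped, f)
    } else if (is.na(vx) || is.na(vy)) {
      den <- den + 0.5
      used <- c(used, f)
    } else {
      bx <- bits(vx); by <- bits(vy)
      num <- num + sum(bx & by)
      den <- den + sum(bx | by)
      used <- c(used, f)
    }
  }
  if (den == 0)
    stop2("similarity undefined for pair (", x, ", ", y,
          "): denominator is zero")
  structure(list(numerator = num, denominator = den,
                 similarity = num / den, distance = 1 - num / den,
                 features_used = used, features_skipped = skipped),
            class = "tanimoto_similarity")
}

#' @export
print.tanimoto_similarity <- function(x, ...) {
  cat(sprintf("Tanimoto-like similarity %.4f (= %g / %g), distance %.4f\n",
              x$similarity, x$numerator, x$denominator, x$distance))
  invisible(x)
}

#' Feature distance matrix over all strain pairs
#'
#' Symmetric matrix of 1 - similarity with zero diagonal. Pairs whose
#' similarity is undefined (every feature unknown in at least one of the
#' two) abort construction with the offending pairs listed, unless
#' \code{allow_missing} substitutes \code{missing_distance}.
#'
#' @param ft a \code{\link{feature_table}}
#' @param allow_missing substitute a fixed distance for undefined pairs
#' @param missing_distance the substituted distance (default 1, maximal)
#' @return labelled symmetric distance matrix
#' @export
feature_distance_matrix <- function(ft, allow_missing = FALSE,
                                    missing_distance = 1) {
  stopifnot(inherits(ft, "feature_table"))
  g <- rownames(ft$values)
  if (length(g) < 2) stop2("need at least 2 genomes")
  d <- matrix(0, length(g), length(g), dimnames = list(g, g))
  undefined <- character()
  for (i in seq_along(g)[-length(g)]) for (j in (i + 1):length(g)) {
    res <- tryCatch(tanimoto_similarity(ft, g[i], g[j]), error = function(e) NULL)
    if (is.null(res)) {
      undefined <- c(undefined, paste(g[i], g[j], sep = "/"))
      d[i, j] <- d[j, i] <- missing_distance
    } else {
      d[i, j] <- d[j, i] <- res$distance
    }
  }
  if (length(undefined) && !allow_missing)
    stop2("similarity undefined for pair(s): ",
          paste(undefined, collapse = ", "),
          " (set allow_missing = TRUE to substitute a maximal distance)")
  d
}

#' Per-feature count of genomes with known value
#'
#' @param ft a \code{\link{feature_table}}
#' @return named integer vector, one count per feature
#' @export
known_info_counts <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  colSums(!is.na(ft$values))
}

#' Read / write a feature table
#'
#' TSV with one row per genome (first column \code{genome_id}) and one
#' column per feature; a cell lists present subcategories separated by
#' \code{";"} (e.g. \code{"sea;fresh"}), an empty cell is a known all-zero
#' value, and \code{"u"} marks unknown. The subcategory roster per feature
#' must be supplied (the file stores names, not positions).
#'
#' @param path file path
#' @param features named list: feature name -> subcategory names
#' @export
read_feature_table <- function(path, features) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (names(df)[1] != "genome_id") stop2("first column must be genome_id")
  if (!identical(names(df)[-1], names(features)))
    stop2("file features must match the supplied roster (same order)")
  vals <- matrix(NA_character_, nrow(df), length(features),
                 dimnames = list(df$genome_id, names(features)))
  for (f in names(features)) {
    subs <- features[[f]]
    for (i in seq_len(nrow(df))) {
      cell <- df[i, f]
      if (identical(cell, "u")) next
      present <- if (nzchar(cell)) strsplit(cell, ";", fixed = TRUE)[[1]]
                 else character()
      bad <- setdiff(present, subs)
      if (length(bad))
        stop2("feature '", f, "': unknown subcategory ", paste(bad, collapse = ","))
      vals[i, f] <- paste(as.integer(subs %in% present), collapse = "")
    }
  }
  feature_table(features, vals)
}

#' @rdname read_feature_table
#' @param ft a \code{\link{feature_table}}
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  g <- rownames(ft$values)
  out <- data.frame(genome_id = g, stringsAsFactors = FALSE)
  for (f in names(ft$features)) {
    subs <- ft$features[[f]]
    out[[f]] <- vapply(ft$values[, f], function(v) {
      if (is.na(v)) return("u")
      paste(subs[bits(v) == 1L], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply logical inference rules to a feature table
#'
#' Encodes "logically assumed" values (e.g. unicellular organisms cannot
#' differentiate heterocysts) as explicit, logged rules rather than silent
#' edits. A rule fires for genomes whose \code{when} feature has a 1 in
#' subcategory \code{has}, and sets \code{then} to the given bit string if
#' currently unknown.
#'
#' @param ft a \code{\link{feature_table}}
#' @param rules data.frame with columns \code{when}, \code{has},
#'   \code{then}, \code{value}
#' @param verbose log each applied inference to stderr
#' @return updated \code{feature_table}
#' @export
apply_inference_rules <- function(ft, rules, verbose = FALSE) {
  stopifnot(inherits(ft, "feature_table"), is.data.frame(rules))
  vals <- ft$values
  for (r in seq_len(nrow(rules))) {
    wf <- rules$when[r]; sub <- rules$has[r]
    tf <- rules$then[r]; tv <- rules$value[r]
    if (!wf %in% names(ft$features) || !tf %in% names(ft$features))
      stop2("rule ", r, ": unknown feature")
    k <- match(sub, ft$features[[wf]])
    if (is.na(k)) stop2("rule ", r, ": unknown subcategory '", sub, "'")
    if (nchar(tv) != length(ft$features[[tf]]))
      stop2("rule ", r, ": value length mismatch")
    for (g in rownames(vals)) {
      v <- vals[g, wf]
      if (!is.na(v) && bits(v)[k] == 1L && is.na(vals[g, tf])) {
        vals[g, tf] <- tv
        if (verbose)
          message("inference: ", g, " ", tf, " <- ", tv,
                  " (because ", wf, " has ", sub, ")")
      }
    }
  }
  feature_table(ft$features, vals)
}
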