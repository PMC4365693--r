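# Independent oracles and fixture builders. These deliberately use naive
# set-based implementations, distinct from the package's matrix-based code
# paths, so agreement is evidence of correctness rather than tautology.

# random CLOG table with arbitrary occupancies and occasional paralogs
rand_clog_table <- function(G, n_clogs, seed, paralog_prob = 0.1) {
  withr::with_seed(seed, {
    genomes <- sprintf("g%02d", seq_len(G))
    rows <- lapply(seq_len(n_clogs), function(i) {
      occ <- sample.int(G, 1)
      gs <- sample(genomes, occ)
      gs <- c(gs, gs[stats::runif(occ) < paralog_prob])
      data.frame(clog_id = sprintf("c%04d", i), genome_id = gs,
                 gene_id = sprintf("c%04d_%s_%d", i, gs, seq_along(gs)),
                 stringsAsFactors = FALSE)
    })
    clog_table(do.call(rbind, rows), genomes = genomes)
  })
}

# brute-force set-based classification from the raw member list
oracle_classify <- function(table) {
  sets <- tapply(table$members$genome_id, table$members$clog_id,
                 function(g) unique(g), simplify = FALSE)
  G <- length(table$genomes)
  vapply(sets[table$clog_ids], function(s) {
    if (length(s) == G) "core" else if (length(s) == 1) "unique"
    else "dispensable"
  }, character(1))
}

# Jaccard of CLOG-presence sets straight from the member list
oracle_clog_jaccard <- function(table, x, y) {
  cx <- unique(table$members$clog_id[table$members$genome_id == x])
  cy <- unique(table$members$clog_id[table$members$genome_id == y])
  length(intersect(cx, cy)) / length(union(cx, cy))
}

# exhaustive rarefaction means over all genome subsets of each size
oracle_rarefaction_means <- function(table) {
  G <- length(table$genomes)
  sets <- tapply(table$members$genome_id, table$members$clog_id, unique,
                 simplify = FALSE)
  core <- pan <- numeric(G)
  for (n in seq_len(G)) {
    subs <- utils::combn(table$genomes, n, simplify = FALSE)
    core_vals <- vapply(subs, function(ss)
      sum(vapply(sets, function(s) all(ss %in% s), logical(1))), numeric(1))
    pan_vals <- vapply(subs, function(ss)
      sum(vapply(sets, function(s) any(ss %in% s), logical(1))), numeric(1))
    core[n] <- mean(core_vals)
    pan[n] <- mean(pan_vals)
  }
  list(core = core, pan = pan)
}

# exhaustive mean new-CLOGs-per-step over all G! genome orderings
oracle_new_genes_means <- function(table) {
  G <- length(table$genomes)
  sets <- tapply(table$members$genome_id, table$members$clog_id, unique,
                 simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  all_ord <- perms(table$genomes)
  new_mat <- t(vapply(all_ord, function(ord) {
    seen <- character()
    vapply(seq_len(G), function(n) {
      touched <- names(sets)[vapply(sets, function(s) any(ord[seq_len(n)] %in% s),
                                    logical(1))]
      out <- length(setdiff(touched, seen))
      seen <<- touched
      out
    }, numeric(1))
  }, numeric(G)))
  colMeans(new_mat)
}

# independent Tanimoto-like index over subcategory-name sets (not bits)
oracle_tanimoto <- function(ft, x, y) {
  num <- 0; den <- 0
  for (f in names(ft$features)) {
    subs <- ft$features[[f]]
    vx <- ft$values[x, f]; vy <- ft$values[y, f]
    if (is.na(vx) && is.na(vy)) next
    if (is.na(vx) || is.na(vy)) { den <- den + 0.5; next }
    sx <- subs[strsplit(vx, "")[[1]] == "1"]
    sy <- subs[strsplit(vy, "")[[1]] == "1"]
    num <- num + length(intersect(sx, sy))
    den <- den + length(union(sx, sy))
  }
  if (den == 0) return(NA_real_)
  num / den
}

# random feature table with unknowns
rand_feature_table <- function(G, n_features = 6, unknown_rate = 0.2, seed) {
  withr::with_seed(seed, {
    genomes <- sprintf("s%02d", seq_len(G))
    features <- lapply(seq_len(n_features), function(i)
      sprintf("f%d_sub%d", i, seq_len(sample(1:4, 1))))
    names(features) <- sprintf("f%d", seq_len(n_features))
    vals <- matrix(NA_character_, G, n_features,
                   dimnames = list(genomes, names(features)))
    for (g in genomes) for (f in names(features)) {
      if (stats::runif(1) < unknown_rate) next
      vals[g, f] <- paste(stats::rbinom(length(features[[f]]), 1, 0.5),
                          collapse = "")
    }
    feature_table(features, vals)
  })
}

# random unrooted tree with strictly positive branch lengths and its
# (additive) patristic matrix
rand_additive_matrix <- function(n_leaves, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_leaves, rooted = FALSE)
    tr$edge.length <- stats::runif(length(tr$edge.length), 0.05, 2)
    d <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(d))
    list(tree = tr, d = d[ord, ord])
  })
}
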