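# Synthetic-data generators with known ground truth for every input the
# pipeline consumes. Each generator is a pure function of its parameters
# and seed; emitted structures always satisfy the consuming module's
# invariants.

#' Pan-genome generator specification
#'
#' Describes a synthetic pan-genome: a planted core, a dispensable fraction
#' with a chosen occupancy spectrum, per-genome unique genes, optional
#' clade-specific extra core CLOGs and planted feature-signature CLOGs with
#' decoys.
#'
#' @param G number of genomes
#' @param core_count number of core CLOGs (one gene per genome each)
#' @param dispensable_count number of dispensable CLOGs
#' @param spectrum probability weights over occupancies 2..G-1 (default
#'   proportional to occupancy^-2, mimicking the strongly skewed occupancy
#'   histogram of real pan-genomes); normalized internally
#' @param unique_rate expected number of unique CLOGs per genome
#'   (Poisson-distributed per genome)
#' @param paralog_prob probability that a core CLOG membership carries a
#'   second (paralogous) gene
#' @param clade_extras list of \code{list(genomes =, count =)}: extra CLOGs
#'   covering exactly those genomes (planted clade cores)
#' @param signatures list of \code{list(name =, feature_set =, n_exact =,
#'   n_decoy_superset =, n_decoy_subset =)}
#' @return object of class \code{pan_genome_spec}
#' @export
pan_genome_spec <- function(G, core_count = 100, dispensable_count = 400,
                            spectrum = NULL, unique_rate = 20,
                            paralog_prob = 0, clade_extras = list(),
                            signatures = list()) {
  if (G < 1) stop2("G must be >= 1")
  if (core_count < 0 || dispensable_count < 0 || unique_rate < 0)
    stop2("counts and rates must be >= 0")
  if (paralog_prob < 0 || paralog_prob > 1)
    stop2("paralog_prob must be in [0,1]")
  occ <- if (G >= 3) seq(2L, G - 1L) else integer()
  if (is.null(spectrum)) spectrum <- occ^-2
  if (length(occ)) {
    if (length(spectrum) != length(occ) || any(spectrum < 0) ||
        sum(spectrum) <= 0)
      stop2("spectrum must be ", length(occ),
            " non-negative weights over occupancies 2..G-1")
    spectrum <- spectrum / sum(spectrum)
  } else if (dispensable_count > 0) {
    stop2("dispensable CLOGs need G >= 3")
  }
  genomes <- sprintf("G%02d", seq_len(G))
  for (s in signatures) {
    if (!all(s$feature_set %in% genomes))
      stop2("signature feature_set outside the genome universe")
    if ((s$n_decoy_superset %||% 0) > 0 && length(s$feature_set) >= G)
      stop2("decoy supersets impossible: feature set spans all genomes")
    if ((s$n_decoy_subset %||% 0) > 0 && length(s$feature_set) < 2)
      stop2("decoy subsets impossible: feature set has a single genome")
  }
  for (ce in clade_extras)
    if (!all(ce$genomes %in% genomes))
      stop2("clade_extras genomes outside the universe")
  structure(list(G = G, genomes = genomes, core_count = core_count,
                 dispensable_count = dispensable_count, spectrum = spectrum,
                 unique_rate = unique_rate, paralog_prob = paralog_prob,
                 clade_extras = clade_extras, signatures = signatures),
            class = "pan_genome_spec")
}

#' Generate a synthetic pan-genome with known truth
#'
#' @param spec a \code{\link{pan_genome_spec}}
#' @param seed RNG seed (generation is a pure function of spec + seed)
#' @return list with \code{table} (a \code{\link{clog_table}} over the
#'   spec's universe) and \code{truth} (data.frame clog_id, planted
#'   role, intended class, feature name for signature/decoy CLOGs)
#' @export
gen_pan_genome <- function(spec, seed) {
  stopifnot(inherits(spec, "pan_genome_spec"))
  genomes <- spec$genomes
  G <- spec$G
  acc <- new.env(parent = emptyenv())
  acc$clog <- acc$genome <- list()
  acc$t_clog <- acc$t_role <- acc$t_class <- acc$t_feature <- list()
  emit <- function(cid, gs, role, feature = NA_character_, paralog = 0) {
    if (paralog > 0) {
      extra <- gs[stats::runif(length(gs)) < paralog]
      gs <- c(gs, extra)
    }
    i <- length(acc$clog) + 1L
    acc$clog[[i]] <- rep.int(cid, length(gs))
    acc$genome[[i]] <- gs
    acc$t_clog[[i]] <- cid
    acc$t_role[[i]] <- role
    acc$t_class[[i]] <- if (length(unique(gs)) == G) "core"
                        else if (length(unique(gs)) == 1L) "unique"
                        else "dispensable"
    acc$t_feature[[i]] <- feature
  }
  with_seed(seed, {
    for (i in seq_len(spec$core_count))
      emit(sprintf("core%05d", i), genomes, "core",
           paralog = spec$paralog_prob)
    if (spec$dispensable_count > 0) {
      occ <- seq(2L, G - 1L)
      ks <- sample(occ, spec$dispensable_count, replace = TRUE,
                   prob = spec$spectrum)
      for (i in seq_len(spec$dispensable_count))
        emit(sprintf("disp%05d", i), sample(genomes, ks[i]), "dispensable")
    }
    for (g in genomes) {
      n_u <- stats::rpois(1, spec$unique_rate)
      for (i in seq_len(n_u))
        emit(sprintf("uniq_%s_%04d", g, i), g, "unique")
    }
    for (ci in seq_along(spec$clade_extras)) {
      ce <- spec$clade_extras[[ci]]
      for (i in seq_len(ce$count))
        emit(sprintf("clade%d_%04d", ci, i), as.character(ce$genomes),
             "clade_extra")
    }
    for (s in spec$signatures) {
      fs <- as.character(s$feature_set)
      for (i in seq_len(s$n_exact %||% 0))
        emit(sprintf("sig_%s_%03d", s$name, i), fs, "signature", s$name)
      for (i in seq_len(s$n_decoy_superset %||% 0)) {
        extra <- sample(setdiff(genomes, fs), 1)
        emit(sprintf("decoySup_%s_%03d", s$name, i), c(fs, extra),
             "decoy_superset", s$name)
      }
      for (i in seq_len(s$n_decoy_subset %||% 0)) {
        drop <- sample(fs, 1)
        emit(sprintf("decoySub_%s_%03d", s$name, i), setdiff(fs, drop),
             "decoy_subset", s$name)
      }
    }
  })
  genome_col <- unlist(acc$genome, use.names = FALSE) %||% character()
  # per-genome running gene counters give unique, reproducible gene ids
  gene_col <- character(length(genome_col))
  for (g in genomes) {
    idx <- which(genome_col == g)
    gene_col[idx] <- sprintf("%s_g%05d", g, seq_along(idx))
  }
  members <- data.frame(clog_id = unlist(acc$clog, use.names = FALSE) %||%
                          character(),
                        genome_id = genome_col, gene_id = gene_col,
                        stringsAsFactors = FALSE)
  truth <- data.frame(clog_id = unlist(acc$t_clog) %||% character(),
                      role = unlist(acc$t_role) %||% character(),
                      class = unlist(acc$t_class) %||% character(),
                      feature = unlist(acc$t_feature) %||% character(),
                      stringsAsFactors = FALSE)
  list(table = clog_table(members, genomes = genomes), truth = truth)
}

#' Calibrated open-pangenome generator specification
#'
#' The desk-scale synthetic study condition: 20 genomes, 150 core CLOGs,
#' 1200 dispensable CLOGs with the default occupancy^-2 spectrum and 140
#' unique CLOGs per genome on average. The unique rate was calibrated once
#' by pilot simulation so that the new-genes-per-genome power law fitted on
#' this pan-genome recovers alpha close to 0.35, the regime of a strongly
#' open pan-genome.
#'
#' @param ... overrides passed to \code{\link{pan_genome_spec}}
#' @export
calibrated_pan_spec <- function(...) {
  args <- utils::modifyList(
    list(G = 20, core_count = 150, dispensable_count = 1200,
         unique_rate = 140),
    list(...))
  do.call(pan_genome_spec, args)
}

#' Default 13-feature phenotype roster
#'
#' Emulates the structure of a curated cyanobacterial feature catalogue:
#' 13 ecological/morphological/physiological features, each with its
#' subcategories.
#'
#' @export
default_features <- function() {
  list(habitat = c("sea", "ground", "fresh_water", "salt_meadow", "host",
                   "water_surface", "coast", "mud", "hot_spring"),
       morphology = c("unicellular", "filamentous", "colonial"),
       cell_shape = c("coccoid", "rod", "spiral"),
       motility = c("gliding", "swimming"),
       nitrogen_fixation = "nif",
       heterocysts = "het",
       akinetes = "aki",
       hormogonia = "hor",
       thermophilic = "thermo",
       halotolerant = "halo",
       toxin_production = c("microcystin", "saxitoxin", "other"),
       pigmentation = c("phycoerythrin", "phycocyanin"),
       symbiosis = "symbiotic")
}

#' Generate a clade-structured synthetic feature table
#'
#' Genomes within a clade share the clade's fingerprint; entries are
#' independently masked to unknown at \code{unknown_rate}.
#'
#' @param clades named list partitioning the genome ids
#' @param features named list feature -> subcategory names (default
#'   \code{\link{default_features}})
#' @param fingerprints optional list: clade -> named character vector of
#'   bit strings per feature; random Bernoulli(0.5) bits when NULL
#' @param unknown_rate probability an entry is masked to unknown, in [0,1)
#' @param seed RNG seed
#' @return list with \code{table} (a \code{\link{feature_table}}) and
#'   \code{truth} (clade assignment, fingerprints, unknown mask)
#' @export
gen_feature_table <- function(clades, features = default_features(),
                              fingerprints = NULL, unknown_rate = 0.1,
                              seed) {
  stopifnot(is.list(clades), !is.null(names(clades)))
  genomes <- unlist(clades, use.names = FALSE)
  if (anyDuplicated(genomes)) stop2("clades must partition the genomes")
  if (unknown_rate < 0 || unknown_rate >= 1)
    stop2("unknown_rate must be in [0,1)")
  with_seed(seed, {
    if (is.null(fingerprints)) {
      fingerprints <- lapply(clades, function(cl)
        vapply(features, function(subs)
          paste(stats::rbinom(length(subs), 1, 0.5), collapse = ""),
          character(1)))
    }
    vals <- matrix(NA_character_, length(genomes), length(features),
                   dimnames = list(genomes, names(features)))
    clade_of <- stats::setNames(rep(names(clades), lengths(clades)), genomes)
    for (g in genomes) vals[g, ] <- fingerprints[[clade_of[g]]][names(features)]
    mask <- matrix(stats::runif(length(vals)) < unknown_rate,
                   nrow(vals), ncol(vals), dimnames = dimnames(vals))
    vals[mask] <- NA_character_
  })
  list(table = feature_table(features, vals),
       truth = list(clade_of = clade_of, fingerprints = fingerprints,
                    unknown_mask = mask))
}

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Evolve single-copy protein families along a known tree
#'
#' For each CLOG a uniform-random ancestor sequence is evolved
#' independently down the tree: on a branch of length b each site
#' substitutes with probability 1 - exp(-b * rate), replacement drawn
#' uniformly from the other 19 residues (no indels, so the gap-free global
#' alignment is optimal and identity expectations are analytic; the
#' stationary identity of two long-separated sequences is 1/20).
#'
#' @param tree an \code{ape} \code{phylo} with branch lengths (the truth)
#' @param n_clogs number of single-copy families
#' @param protein_length residues per protein
#' @param rate substitutions per site per unit branch length
#' @param seed RNG seed
#' @return list with \code{sequences} (named character vector gene_id ->
#'   sequence), \code{table} (single-copy \code{\link{clog_table}} over the
#'   leaf genomes) and \code{tree}
#' @export
gen_divergent_proteins <- function(tree, n_clogs, protein_length = 200,
                                   rate = 1, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop2("tree needs branch lengths")
  leaves <- tree$tip.label
  n_tip <- length(leaves)
  n_node <- n_tip + tree$Nnode
  edges <- ape::reorder.phylo(tree, "cladewise")
  root <- unique(edges$edge[, 1])[!unique(edges$edge[, 1]) %in%
                                    edges$edge[, 2]]
  seqs <- character()
  rows <- list()
  with_seed(seed, {
    for (k in seq_len(n_clogs)) {
      node_seq <- vector("list", n_node)
      node_seq[[root]] <- sample.int(20L, protein_length, replace = TRUE)
      for (e in seq_len(nrow(edges$edge))) {
        from <- edges$edge[e, 1]; to <- edges$edge[e, 2]
        p_sub <- 1 - exp(-edges$edge.length[e] * rate)
        s <- node_seq[[from]]
        hit <- which(stats::runif(protein_length) < p_sub)
        if (length(hit)) {
          shift <- sample.int(19L, length(hit), replace = TRUE)
          s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
        }
        node_seq[[to]] <- s
      }
      for (i in seq_len(n_tip)) {
        gid <- sprintf("%s_c%04d", leaves[i], k)
        seqs[gid] <- paste(AA_ALPHABET20[node_seq[[i]]], collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          clog_id = sprintf("P%04d", k), genome_id = leaves[i],
          gene_id = gid, stringsAsFactors = FALSE)
      }
    }
  })
  list(sequences = seqs,
       table = clog_table(do.call(rbind, rows), genomes = leaves),
       tree = tree)
}

#' Generate synthetic beta-barrel evidence with known truth
#'
#' Each protein carries a true barrel/non-barrel label at
#' \code{prevalence}. Every predictor votes on a true barrel with its
#' sensitivity and on a non-barrel with 1 - specificity; the pHMM route
#' behaves likewise and attaches a family from \code{families} when it
#' fires. Non-barrel proteins receive non-barrel Pfam coverage leaving no
#' stretch of 80+ uncovered residues, barrels remain uncovered. Proteins
#' are grouped into CLOGs of \code{clog_size} by true label, so in the
#' noiseless limit every CLOG vote is unanimous.
#'
#' @param n_proteins number of proteins
#' @param prevalence fraction of true barrels (default 0.03, a realistic
#'   outer-membrane share of a proteome)
#' @param sensitivities,specificities named per-predictor rates in [0,1]
#' @param phmm_sensitivity,phmm_specificity rates for the profile-HMM route
#' @param protein_length residues per protein
#' @param clog_size proteins per CLOG
#' @param families family labels attached to pHMM hits
#' @param seed RNG seed
#' @return list with \code{evidence} (a \code{\link{barrel_evidence}}),
#'   \code{table} (the matching \code{\link{clog_table}}) and \code{truth}
#'   (logical is_barrel per protein)
#' @export
gen_barrel_evidence <- function(n_proteins,
                                prevalence = 0.03,
                                sensitivities = c(BOMP = 0.80, KNN = 0.85,
                                                  TMBetaDisc = 0.75),
                                specificities = c(BOMP = 0.99, KNN = 0.95,
                                                  TMBetaDisc = 0.97),
                                phmm_sensitivity = 0.90,
                                phmm_specificity = 0.995,
                                protein_length = 300,
                                clog_size = 4,
                                families = c("Omp85", "LptD", "OprB",
                                             "TolC", "FhaC"),
                                seed) {
  rates <- c(prevalence, sensitivities, specificities, phmm_sensitivity,
             phmm_specificity)
  if (any(rates < 0 | rates > 1)) stop2("all rates must be in [0,1]")
  if (!identical(sort(names(sensitivities)), sort(names(specificities))))
    stop2("sensitivities and specificities must name the same predictors")
  preds <- names(sensitivities)
  with_seed(seed, {
    is_barrel <- stats::runif(n_proteins) < prevalence
    pid <- sprintf("prot%05d", seq_len(n_proteins))
    genome <- sprintf("G%02d", (seq_len(n_proteins) %% 8L) + 1L)
    votes <- lapply(seq_len(n_proteins), function(i) {
      p <- if (is_barrel[i]) sensitivities[preds]
           else 1 - specificities[preds]
      preds[stats::runif(length(preds)) < p]
    })
    phmm <- lapply(seq_len(n_proteins), function(i) {
      p <- if (is_barrel[i]) phmm_sensitivity else 1 - phmm_specificity
      if (stats::runif(1) < p) {
        data.frame(family = sample(families, 1), start = 10L,
                   end = as.integer(protein_length - 10L),
                   evalue = 10^-stats::runif(1, 10, 50),
                   bits = stats::runif(1, 50, 500),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(family = character(), start = integer(), end = integer(),
                   evalue = numeric(), bits = numeric(),
                   stringsAsFactors = FALSE)
      }
    })
    pfam <- lapply(seq_len(n_proteins), function(i) {
      if (is_barrel[i]) matrix(numeric(0), 0, 2)
      else {
        # tile the protein with domains separated by sub-threshold gaps
        starts <- seq(1, protein_length, by = 100)
        cbind(starts, pmin(starts + 59, protein_length))
      }
    })
    # CLOGs grouped by true label so unanimity holds in the noiseless limit
    mk_clogs <- function(idx, prefix) {
      if (!length(idx)) return(stats::setNames(character(0), character(0)))
      grp <- ceiling(seq_along(idx) / clog_size)
      stats::setNames(sprintf("%s%04d", prefix, grp), pid[idx])
    }
    clog_of <- c(mk_clogs(which(is_barrel), "BCL"),
                 mk_clogs(which(!is_barrel), "NCL"))
    clog_id <- unname(clog_of[pid])
  })
  members <- data.frame(clog_id = clog_id, genome_id = genome,
                        gene_id = pid, stringsAsFactors = FALSE)
  ev <- barrel_evidence(pid, genome, rep(protein_length, n_proteins),
                        votes, phmm, pfam, clog_id,
                        rep(FALSE, n_proteins))
  list(evidence = ev,
       table = clog_table(members,
                          genomes = sort(unique(genome))),
       truth = stats::setNames(is_barrel, pid))
}
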