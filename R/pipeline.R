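# Config-driven orchestration of an end-to-end run: classify -> rarefy ->
# trees -> signatures -> barrels -> functional profile, with a manifest
# recording inputs, parameters, seeds and output checksums so a run is
# fully reproducible and auditable.

#' Read and validate a pipeline run configuration
#'
#' YAML file with blocks \code{inputs} (paths: \code{clogs} + optional
#' \code{clog_format}, \code{registry}; optional \code{features},
#' \code{feature_set}, \code{hits}, \code{evidence}, \code{barrel_clogs},
#' \code{annotation}), \code{output_dir}, \code{seed}, and an optional
#' \code{params} block (\code{repetitions}, \code{permutations},
#' \code{bootstrap}, \code{min_support}, \code{min_coverage},
#' \code{max_evalue}). Unknown keys are rejected; referenced input paths
#' must exist.
#'
#' @param path YAML config file
#' @return validated config list of class \code{run_config}
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg, dir = dirname(path))
}

#' @rdname read_run_config
#' @param cfg a configuration list (as from \code{yaml::read_yaml})
#' @param dir base directory for resolving relative paths
#' @export
validate_run_config <- function(cfg, dir = ".") {
  known_top <- c("inputs", "output_dir", "seed", "params")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) stop2("unknown config key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$inputs) || is.null(cfg$output_dir) || is.null(cfg$seed))
    stop2("config needs 'inputs', 'output_dir' and 'seed'")
  if (cfg$seed != round(cfg$seed)) stop2("seed must be an integer")
  known_in <- c("clogs", "clog_format", "registry", "features",
                "feature_set", "hits", "evidence", "barrel_clogs",
                "annotation")
  bad <- setdiff(names(cfg$inputs), known_in)
  if (length(bad)) stop2("unknown inputs key(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$inputs$clogs) || is.null(cfg$inputs$registry))
    stop2("inputs must name at least 'clogs' and 'registry'")
  known_par <- c("repetitions", "permutations", "bootstrap", "min_support",
                 "min_coverage", "max_evalue")
  bad <- setdiff(names(cfg$params), known_par)
  if (length(bad)) stop2("unknown params key(s): ", paste(bad, collapse = ", "))
  # resolve and check every referenced path before any stage runs
  for (key in setdiff(names(cfg$inputs), "clog_format")) {
    p <- cfg$inputs[[key]]
    if (!file.exists(p)) {
      p2 <- file.path(dir, p)
      if (!file.exists(p2)) stop2("input '", key, "' not found: ", p)
      cfg$inputs[[key]] <- p2
    }
  }
  structure(cfg, class = "run_config")
}

default_params <- function(params) {
  utils::modifyList(list(repetitions = 1000, permutations = 1000,
                         bootstrap = 100, min_support = 1,
                         min_coverage = 0.80, max_evalue = 1.0e-10),
                    params %||% list())
}

#' Run the pipeline end to end from a configuration
#'
#' Executes the stages in dependency order — classification, rarefaction
#' and power-law fit, CLOG (and, when a feature table is given, feature)
#' distance trees with their patristic correlation, signature mining when
#' a feature strain set is given, beta-barrel categorization when an
#' evidence table is given, COG aggregation when an annotation is given —
#' writing each stage's tables under \code{output_dir} and recording a
#' manifest (parameter echo, seeds, package version, per-output MD5
#' checksums). Re-running the same config reproduces identical checksums.
#'
#' @param config a \code{run_config} or path to a YAML config file
#' @param verbose log stage progress to stderr
#' @return the manifest (invisibly); also written as
#'   \code{output_dir/manifest.yaml}
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  par <- default_params(cfg$params)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  log_ <- function(...) if (verbose) message("[cyanopan] ", ...)

  manifest <- list(package_version = as.character(utils::packageVersion("cyanopan")),
                   seed = seed, params = par, inputs = cfg$inputs,
                   stages = list(), status = "running")
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  finish_stage <- function(name, detail = list()) {
    manifest$stages[[name]] <<- c(list(outputs = basename(outputs)), detail)
  }
  fail <- function(stage, err) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(err)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(err))
  }

  run_stage <- function(name, body) {
    log_("stage: ", name)
    outputs <<- character()
    tryCatch(body(), error = function(e) fail(name, e))
  }

  registry <- read_genome_registry(cfg$inputs$registry)
  tab <- read_clog_table(cfg$inputs$clogs,
                         cfg$inputs$clog_format %||% "orthomcl_groups",
                         genomes = registry$genomes$genome_id)

  cls <- NULL
  run_stage("classify", function() {
    cls <<- classify_clogs(tab)
    emit(data.frame(clog_id = names(cls$class),
                    class = as.character(cls$class),
                    occupancy = unname(cls$occupancy)),
         "classification.tsv")
    profs <- t(vapply(tab$genomes, function(g) genome_profile(tab, cls, g),
                      integer(3)))
    emit(data.frame(genome_id = rownames(profs), profs),
         "genome_profiles.tsv")
    finish_stage("classify", list(counts = as.list(cls$counts)))
  })

  run_stage("rarefaction", function() {
    curve <- rarefy(tab, repetitions = par$repetitions, seed = seed + 1L)
    emit(summary(curve, "core"), "rarefaction_core.tsv")
    emit(summary(curve, "pan"), "rarefaction_pan.tsv")
    nc <- new_genes_per_step(tab, permutations = par$permutations,
                             seed = seed + 2L)
    fit <- fit_power_law(nc, bootstrap = par$bootstrap, seed = seed + 3L)
    emit(data.frame(alpha = fit$alpha, alpha_sd = fit$alpha_sd,
                    kappa = fit$kappa, r_squared = fit$r_squared,
                    open = fit$open), "power_law_fit.tsv")
    finish_stage("rarefaction", list(alpha = fit$alpha))
  })

  run_stage("trees", function() {
    dclog <- clog_distance_matrix(tab)
    write_distance_matrix(dclog, file.path(out_dir, "dist_clog.tsv"))
    outputs <<- c(outputs, file.path(out_dir, "dist_clog.tsv"))
    t_clog <- neighbor_joining(dclog)
    ape::write.tree(t_clog, file.path(out_dir, "tree_clog.nwk"))
    outputs <<- c(outputs, file.path(out_dir, "tree_clog.nwk"))
    detail <- list()
    if (!is.null(cfg$inputs$features)) {
      feat <- read_feature_table(cfg$inputs$features, default_features())
      dfeat <- feature_distance_matrix(feat, allow_missing = TRUE)
      write_distance_matrix(dfeat, file.path(out_dir, "dist_feature.tsv"))
      t_feat <- neighbor_joining(dfeat)
      ape::write.tree(t_feat, file.path(out_dir, "tree_feature.nwk"))
      outputs <<- c(outputs, file.path(out_dir, "dist_feature.tsv"),
                    file.path(out_dir, "tree_feature.nwk"))
      detail$clog_vs_feature_correlation <-
        patristic_correlation(t_clog, t_feat)
    }
    finish_stage("trees", detail)
  })

  if (!is.null(cfg$inputs$feature_set)) {
    run_stage("signatures", function() {
      fs <- read_feature_strain_set(cfg$inputs$feature_set)
      exact <- exact_feature_clogs(tab, fs)
      rel <- relaxed_feature_clogs(tab, fs,
                                   min_support = par$min_support)
      emit(data.frame(clog_id = rel$clog_ids), "feature_clogs.tsv")
      detail <- list(exact = length(exact))
      if (!is.null(cfg$inputs$hits)) {
        hits <- read_hit_table(cfg$inputs$hits)
        genes <- tab$members$gene_id[tab$members$clog_id %in% exact]
        filt <- specificity_filter(hits, min_coverage = par$min_coverage,
                                   max_evalue = par$max_evalue,
                                   queries = genes)
        emit(data.frame(gene_id = genes,
                        is_signature = unname(filt$is_signature[genes])),
             "signature_genes.tsv")
        detail$signatures <- sum(filt$is_signature[genes])
      }
      finish_stage("signatures", detail)
    })
  }

  if (!is.null(cfg$inputs$evidence)) {
    run_stage("barrels", function() {
      ev <- read_barrel_evidence(cfg$inputs$evidence)
      btab <- if (!is.null(cfg$inputs$barrel_clogs))
        read_clog_table(cfg$inputs$barrel_clogs, "tsv") else NULL
      calls <- categorize_barrels(ev, btab)
      emit(calls, "barrel_calls.tsv")
      finish_stage("barrels",
                   list(categories = as.list(table(calls$category))))
    })
  }

  if (!is.null(cfg$inputs$annotation)) {
    run_stage("functional", function() {
      ann <- read_annotation_map(cfg$inputs$annotation)
      core_genes <- clade_core_genes(tab, tab$genomes, tab$genomes[1])
      agg <- aggregate_categories(core_genes, ann)
      emit(data.frame(category = names(agg$counts),
                      count = unname(agg$counts)),
           "core_cog_counts.tsv")
      finish_stage("functional",
                   list(unassigned = agg$unassigned))
    })
  }

  manifest$status <- "complete"
  all_out <- list.files(out_dir, full.names = TRUE)
  all_out <- all_out[basename(all_out) != "manifest.yaml"]
  manifest$checksums <- as.list(tools::md5sum(all_out))
  names(manifest$checksums) <- basename(all_out)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log_("run complete: ", length(all_out), " outputs in ", out_dir)
  invisible(manifest)
}
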