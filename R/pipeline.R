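# Single-config orchestration of the full analysis: curation summary ->
# DE gene-set integration -> network diffusion, CV and prioritisation,
# with intermediate tables and a machine-readable JSON report.

default_run_config <- function() {
  list(
    observations = NULL,      # path to curated observation table
    de_tables = NULL,         # character vector of DE table paths
    de_species = NULL,        # per-table species (recycled), "human"/"animal"
    network = NULL,           # path to edge list
    ortholog_map = NULL,      # optional two-column TSV
    protein_coding = NULL,    # optional one-column gene list
    tractability = NULL,      # optional two-column TSV gene -> label
    fc_threshold = 1.5,
    p_threshold = 0.05,
    min_de = 3L,
    min_interactions = 4L,
    r = 0.3,
    tol = 1e-8,
    max_iter = 1000L,
    k = 5L,
    repeats = 10L,
    rng_seed = 1L,
    universe = "per_dataset",
    wilcoxon = "signed_rank",
    seed_effects = c("protective", "detrimental", "ambiguous", "mixed"),
    cross_approach_method = "consensus"
  )
}

#' Read and validate a pipeline run configuration
#'
#' Reads a YAML key-value file, fills unset keys with package defaults and
#' validates paths and threshold ranges. `overrides` (a named list, e.g.
#' from CLI flags) take precedence over the file.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list of config values overriding the file.
#' @return Validated config list (class `run_config`).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_schema("config file not found: ", path)
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_schema("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  for (key in c("observations", "network", "ortholog_map", "protein_coding",
                "tractability")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_schema("config path for '", key, "' does not exist: ", cfg[[key]])
    }
  }
  if (!is.null(cfg$de_tables)) {
    missing <- cfg$de_tables[!file.exists(cfg$de_tables)]
    if (length(missing)) {
      stop_schema("DE table path(s) do not exist: ",
                  paste(missing, collapse = ", "))
    }
  }
  if (cfg$fc_threshold < 1) stop_schema("fc_threshold must be >= 1")
  if (cfg$p_threshold < 0 || cfg$p_threshold > 1) {
    stop_schema("p_threshold must be in [0, 1]")
  }
  if (!(cfg$r > 0 && cfg$r <= 1)) stop_schema("r must be in (0, 1]")
  if (cfg$k < 2) stop_schema("k must be >= 2")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(...) message("[oagenes] ", ...)

#' Run the full analysis pipeline from a configuration
#'
#' Executes the stages in order — curation summary, DE gene-set
#' integration, network diffusion with cross-validation and candidate
#' prioritisation — writing intermediate tables to `out_dir` and returning
#' a machine-readable report. A stage whose inputs are not configured is
#' skipped with an explicit notice in the report; a stage failure aborts
#' with the stage name while earlier outputs are retained.
#'
#' @param config A config list from [read_run_config()] (or a path to a
#'   YAML config file).
#' @param out_dir Output directory, created if needed.
#' @return Object of class `run_report` (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config, out_dir = "oagenes_out") {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package_version = as.character(utils::packageVersion("oagenes")),
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  summaries <- NULL
  # ---- curation -------------------------------------------------------
  if (is.null(config$observations)) {
    log_msg("curation: skipped (no observation table configured)")
    report$stages$curation <- "skipped"
  } else {
    run_stage("curation", function() {
      log_msg("curation: reading ", config$observations)
      obs <- read_observations(config$observations)
      summaries <<- gene_summaries(obs)
      counts <- summary_counts(obs)
      consistency <- consistency_report(
        obs, cross_approach_method = config$cross_approach_method)
      write_tsv(summaries, file.path(out_dir, "gene_summary.tsv"))
      jsonlite::write_json(unclass(consistency),
                           file.path(out_dir, "consistency.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$curation <<- "ok"
      report$summary_counts <<- unclass(counts)
      report$consistency <<- unclass(consistency)
    })
  }

  # ---- expression -----------------------------------------------------
  gene_sets <- NULL
  if (is.null(config$de_tables) || length(config$de_tables) == 0L) {
    log_msg("expression: skipped (no DE tables configured)")
    report$stages$expression <- "skipped"
  } else {
    run_stage("expression", function() {
      log_msg("expression: ", length(config$de_tables), " DE table(s)")
      orth <- if (!is.null(config$ortholog_map)) {
        read_tsv(config$ortholog_map)
      } else NULL
      coding <- if (!is.null(config$protein_coding)) {
        toupper(read_tsv(config$protein_coding)[[1L]])
      } else NULL
      species <- rep_len(config$de_species %||% "human",
                         length(config$de_tables))
      gene_sets <<- lapply(seq_along(config$de_tables), function(i) {
        tab <- read_de_table(config$de_tables[[i]], species = species[[i]])
        gs <- significant_gene_sets(tab, config$fc_threshold,
                                    config$p_threshold)
        for (fld in c("up", "down", "universe")) {
          gs[[fld]] <- map_to_human(gs[[fld]], ortholog_map = orth)
          if (!is.null(coding)) gs[[fld]] <- intersect(gs[[fld]], coding)
        }
        gs
      })
      if (!is.null(summaries)) {
        ref_sum <- summaries
        if (!is.null(coding)) {
          ref_sum <- ref_sum[ref_sum$gene %in% coding, , drop = FALSE]
        }
        labelled <- ref_sum$gene[ref_sum$consensus != "no_effect"]
        uni <- if (identical(config$universe, "per_dataset")) {
          "per_dataset"
        } else {
          unique(unlist(lapply(gene_sets, `[[`, "universe")))
        }
        ov <- overlap_tests(gene_sets, labelled, universe = uni)
        mat <- overlap_effect_matrix(gene_sets, ref_sum,
                                     alpha = config$p_threshold)
        write_tsv(ov, file.path(out_dir, "overlap_tests.tsv"))
        write_tsv(mat, file.path(out_dir, "overlap_effect_matrix.tsv"))
        report$overlap_tests <<- ov
        report$overlap_effect_matrix <<- mat
      }
      report$stages$expression <<- "ok"
    })
  }

  # ---- diffusion ------------------------------------------------------
  if (is.null(config$network)) {
    log_msg("diffusion: skipped (no network configured)")
    report$stages$diffusion <- "skipped"
  } else if (is.null(summaries)) {
    log_msg("diffusion: skipped (no curated genes to seed from)")
    report$stages$diffusion <- "skipped"
  } else {
    run_stage("diffusion", function() {
      log_msg("diffusion: reading network ", config$network)
      net <- read_network(config$network)
      seeds <- summaries$gene[summaries$consensus %in% config$seed_effects]
      seeds <- intersect(seeds, net$nodes)
      if (length(seeds) == 0L) stop("no seed genes present in the network")
      sc <- diffuse(net, seeds, r = config$r, tol = config$tol,
                    max_iter = config$max_iter)
      ranks <- rank_genes(sc, exclude = seeds)
      write_tsv(data.frame(gene = names(ranks), rank = unname(ranks),
                           score = unname(sc$scores[names(ranks)])),
                file.path(out_dir, "network_ranks.tsv"))
      cv <- cross_validate(net, seeds, k = config$k,
                           repeats = config$repeats, r = config$r,
                           tol = config$tol, max_iter = config$max_iter,
                           rng_seed = config$rng_seed)
      sep <- cv_separation_test(cv)
      cv_summary <- list(
        median_heldout_rank = stats::median(cv$heldout_ranks),
        median_unlabelled_rank = stats::median(cv$unlabelled_ranks),
        n_nodes = cv$n_nodes, n_seeds = cv$n_seeds,
        k = cv$k, repeats = cv$repeats,
        rank_test_p = sep$p
      )
      jsonlite::write_json(cv_summary, file.path(out_dir, "cv_summary.json"),
                           auto_unbox = TRUE, digits = NA)

      de_counts <- integer()
      if (!is.null(gene_sets)) {
        human <- Filter(function(g) identical(g$species, "human"), gene_sets)
        if (length(human)) {
          hits <- unlist(lapply(human, function(g) unique(c(g$up, g$down))))
          de_counts <- table(hits)
          de_counts <- stats::setNames(as.integer(de_counts),
                                       names(de_counts))
        }
      }
      labelled <- summaries$gene[summaries$consensus != "no_effect"]
      ic <- count_oa_interactions(net, names(ranks),
                                  intersect(labelled, net$nodes))
      tract <- if (!is.null(config$tractability)) {
        tt <- read_tsv(config$tractability)
        stats::setNames(as.character(tt[[2L]]), toupper(tt[[1L]]))
      } else NULL
      cand <- prioritise(ranks, de_counts, ic, known = labelled,
                         min_de = config$min_de,
                         min_interactions = config$min_interactions,
                         tractability = tract)
      write_tsv(cand, file.path(out_dir, "candidates.tsv"))
      report$stages$diffusion <<- "ok"
      report$cv_summary <<- cv_summary
      report$candidates <<- cand
    })
  }

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (config ", substr(x$config_hash, 1, 8), ")\n",
      sep = "")
  for (st in names(x$stages)) {
    cat(sprintf("  %-11s %s\n", paste0(st, ":"), x$stages[[st]]))
  }
  if (!is.null(x$cv_summary)) {
    cat(sprintf("  CV: median held-out rank %.1f vs unlabelled %.1f (of %d), p = %.3g\n",
                x$cv_summary$median_heldout_rank,
                x$cv_summary$median_unlabelled_rank,
                x$cv_summary$n_nodes, x$cv_summary$rank_test_p))
  }
  if (!is.null(x$candidates)) {
    cat(sprintf("  %d prioritised candidate(s)\n", nrow(x$candidates)))
  }
  invisible(x)
}
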