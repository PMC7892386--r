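# Synthetic-data generators with known ground truth: curated observation
# tables with a controllable consistency rate, scale-free networks with a
# planted module, and DE result tables with controllable enrichment.
# Defaults emulate the curated animal-model OA corpus (mostly
# single-study genes, ~70% cross-study consistency, surgical and
# spontaneous models dominant).

flip_effect <- function(e) {
  ifelse(e == "protective", "detrimental",
         ifelse(e == "detrimental", "protective", e))
}

# observed_effect that makes infer_effect(activity, observed) == target
observed_for <- function(activity, target) {
  ifelse(target %in% c("no_effect", "mixed"), target,
         ifelse(activity == "decrease", flip_effect(target), target))
}

#' Generate a synthetic curated observation table
#'
#' Assigns every gene a true effect and draws a per-gene consistency flag
#' with probability `consistency_rate`. A consistent gene's observations
#' all infer the true effect; an inconsistent gene's observations alternate
#' between the true and the contradicting direction within each approach
#' stratum (no-effect genes alternate between the two directions), so a
#' gene studied at least twice in an approach is detected as inconsistent
#' there and the consistency rate measured by [consistency_report()] over
#' multi-study genes recovers `consistency_rate` up to binomial sampling
#' error. The output table uses the exact schema consumed by
#' [read_observations()]; each observation carries its own publication
#' identifier.
#'
#' @param n_genes Number of genes (ignored when `genes` is given).
#' @param genes Optional character vector of gene symbols to curate (e.g.
#'   nodes of a [synth_network()] graph, so that curated genes exist in the
#'   network); by default synthetic symbols are generated.
#' @param obs_per_gene Either a function of `n` returning integer counts, a
#'   vector of counts recycled over genes, or a single integer. The default
#'   (1 + Poisson(0.8)) makes single-study genes the most common case.
#' @param consistency_rate Probability that a gene's observations are
#'   mutually consistent (all inferring its true effect).
#' @param approach_mix Named probabilities over genetic / exogenous.
#' @param model_mix Named probabilities over the model categories.
#' @param effect_mix Named probabilities over true gene effects
#'   (protective / detrimental / no_effect).
#' @param rng_seed Integer seed; identical seeds give identical tables.
#' @return List with `observations` (an `oa_observations` data frame) and
#'   `truth` (true per-gene effects and the full parameter record).
#' @export
synth_observations <- function(n_genes = 500L, genes = NULL,
                               obs_per_gene = function(n) 1L + stats::rpois(n, 0.8),
                               consistency_rate = 0.7,
                               approach_mix = c(genetic = 0.63, exogenous = 0.37),
                               model_mix = c(surgical = 0.45, spontaneous = 0.30,
                                             high_fat_diet = 0.05, chemical = 0.08,
                                             mechanical = 0.04,
                                             genetic_susceptibility = 0.05,
                                             other = 0.03),
                               effect_mix = c(protective = 0.40,
                                              detrimental = 0.45,
                                              no_effect = 0.15),
                               rng_seed = 1L) {
  if (consistency_rate < 0 || consistency_rate > 1) {
    stop("consistency_rate must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(genes)) n_genes <- length(genes)
  params <- list(n_genes = n_genes, consistency_rate = consistency_rate,
                 approach_mix = approach_mix, model_mix = model_mix,
                 effect_mix = effect_mix, rng_seed = rng_seed)
  if (n_genes == 0L) {
    obs <- read_observations_template()
    return(list(observations = obs,
                truth = list(true_gene_effects = character(), params = params)))
  }
  with_seed(rng_seed, {
    genes <- if (is.null(genes)) sprintf("SYNG%04d", seq_len(n_genes)) else
      toupper(genes)
    true_eff <- sample(names(effect_mix), n_genes, replace = TRUE,
                       prob = effect_mix)
    names(true_eff) <- genes
    counts <- if (is.function(obs_per_gene)) {
      pmax(1L, as.integer(obs_per_gene(n_genes)))
    } else {
      pmax(1L, as.integer(rep_len(obs_per_gene, n_genes)))
    }
    n_obs <- sum(counts)
    gene <- rep(genes, counts)
    gene_consistent <- stats::runif(n_genes) < consistency_rate
    names(gene_consistent) <- genes
    approach <- sample(names(approach_mix), n_obs, replace = TRUE,
                       prob = approach_mix)
    # per-observation inferred-effect target: true effect throughout for
    # consistent genes; alternating directions within each (gene, approach)
    # stratum for inconsistent genes
    target <- rep(true_eff, counts)
    strata <- paste(gene, approach)
    within_idx <- stats::ave(seq_len(n_obs), strata, FUN = seq_along)
    incons <- !gene_consistent[gene]
    base <- ifelse(target == "no_effect", "protective", target)
    alt <- ifelse(within_idx %% 2L == 1L, base, flip_effect(base))
    target[incons] <- alt[incons]
    activity <- sample(c("increase", "decrease"), n_obs, replace = TRUE)
    observed <- observed_for(activity, target)
    intervention <- ifelse(
      approach == "genetic",
      ifelse(activity == "decrease", "Knockout", "Overexpression"),
      ifelse(activity == "decrease", "Antibody", "Protein")
    )
    model <- sample(names(model_mix), n_obs, replace = TRUE, prob = model_mix)
    obs <- data.frame(
      gene = gene,
      pmid = sprintf("PM%06d", seq_len(n_obs)),
      intervention = intervention,
      activity_change = activity,
      approach = approach,
      model = model,
      model_subtype = "",
      observed_effect = observed,
      specificity = "Global",
      species = "Mouse",
      stringsAsFactors = FALSE
    )
    class(obs) <- c("oa_observations", "data.frame")
    list(observations = obs,
         truth = list(true_gene_effects = true_eff, params = params))
  })
}

read_observations_template <- function() {
  obs <- data.frame(gene = character(), pmid = character(),
                    intervention = character(), activity_change = character(),
                    approach = character(), model = character(),
                    model_subtype = character(), observed_effect = character(),
                    specificity = character(), species = character(),
                    stringsAsFactors = FALSE)
  class(obs) <- c("oa_observations", "data.frame")
  obs
}

#' Generate a scale-free-like network with a planted module
#'
#' Grows a preferential-attachment graph and plants a densely connected
#' module by adding each within-module edge independently with probability
#' `intra_module_edge_boost`. With boost 0 the module is topologically
#' indistinguishable from the background (negative control); with a high
#' boost it approaches a clique. The output is simplified (no self-loops or
#' multi-edges) and guaranteed connected: if planting disconnects nothing
#' but the base graph came apart, bridging edges to the largest component
#' are added and counted.
#'
#' @param n_nodes Number of nodes.
#' @param attachment Edges added per new node in the preferential-attachment
#'   growth (controls density).
#' @param module_size Planted module size (< `n_nodes`).
#' @param intra_module_edge_boost Probability of each within-module edge
#'   being added on top of the base graph.
#' @param rng_seed Integer seed.
#' @return List with `edges` (two-column data frame) and `truth` (planted
#'   module members, bridging-edge count, parameters).
#' @export
synth_network <- function(n_nodes = 2000L, attachment = 2L, module_size = 50L,
                          intra_module_edge_boost = 0.3, rng_seed = 1L) {
  if (module_size >= n_nodes) stop("module_size must be < n_nodes",
                                   call. = FALSE)
  params <- list(n_nodes = n_nodes, attachment = attachment,
                 module_size = module_size,
                 intra_module_edge_boost = intra_module_edge_boost,
                 rng_seed = rng_seed)
  with_seed(rng_seed, {
    g <- igraph::sample_pa(n_nodes, power = 1, m = attachment,
                           directed = FALSE)
    igraph::V(g)$name <- sprintf("NODE%05d", seq_len(n_nodes))
    module <- sort(sample(igraph::V(g)$name, module_size))
    if (intra_module_edge_boost > 0 && module_size >= 2L) {
      pairs <- utils::combn(module, 2L)
      add <- stats::runif(ncol(pairs)) < intra_module_edge_boost
      if (any(add)) {
        g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
      }
    }
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    n_bridges <- 0L
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      main <- which.max(comp$csize)
      anchor <- igraph::V(g)$name[comp$membership == main][1L]
      for (ci in setdiff(seq_len(comp$no), main)) {
        v <- igraph::V(g)$name[comp$membership == ci][1L]
        g <- igraph::add_edges(g, c(anchor, v))
        n_bridges <- n_bridges + 1L
      }
    }
    el <- igraph::as_edgelist(g)
    list(edges = data.frame(from = el[, 1L], to = el[, 2L],
                            stringsAsFactors = FALSE),
         truth = list(planted_module = module, n_bridges = n_bridges,
                      params = params))
  })
}

#' Generate synthetic differential-expression result tables
#'
#' Emits DE tables with directly generated adjusted p-values (the pipeline
#' consumes DE results, not raw expression): null genes draw
#' `adj_p ~ Uniform(0, 1)` and small fold changes, signal genes draw
#' Beta-skewed small p-values and fold changes past the usual threshold.
#' Each gene is a signal with base probability `base_signal_rate`; genes in
#' `enriched_set` have their odds of being a signal multiplied by
#' `enrichment_odds` (1 = null calibration). Datasets are independent given
#' the seed.
#'
#' @param n_datasets Number of tables.
#' @param universe Character vector of measured gene identifiers.
#' @param enriched_set Subset of `universe` with elevated signal odds.
#' @param enrichment_odds Odds multiplier, >= 1.
#' @param effect_size_log2fc Mean absolute log2 fold change of signals.
#' @param noise_sd SD of null log2 fold changes (and of signal jitter).
#' @param base_signal_rate Probability that a background gene is a signal.
#' @param signal_direction "both" (random sign), "up" or "down" for the
#'   enriched genes' fold-change direction.
#' @param species Metadata attached to every table.
#' @param rng_seed Integer seed.
#' @return List with `tables` (list of `de_table`) and `truth` (per-dataset
#'   signal gene sets and parameters).
#' @export
synth_de_tables <- function(n_datasets = 6L, universe = sprintf("SYNG%04d", 1:1000),
                            enriched_set = character(), enrichment_odds = 20,
                            effect_size_log2fc = 1.5, noise_sd = 0.4,
                            base_signal_rate = 0.05,
                            signal_direction = c("both", "up", "down"),
                            species = "human", rng_seed = 1L) {
  signal_direction <- match.arg(signal_direction)
  if (enrichment_odds < 1) stop("enrichment_odds must be >= 1", call. = FALSE)
  if (!all(enriched_set %in% universe)) {
    stop("enriched_set must be a subset of the universe", call. = FALSE)
  }
  params <- list(n_datasets = n_datasets, n_universe = length(universe),
                 enrichment_odds = enrichment_odds,
                 effect_size_log2fc = effect_size_log2fc, noise_sd = noise_sd,
                 base_signal_rate = base_signal_rate,
                 signal_direction = signal_direction, rng_seed = rng_seed)
  if (n_datasets == 0L) {
    return(list(tables = list(),
                truth = list(de_enriched_sets = list(), params = params)))
  }
  o0 <- base_signal_rate / (1 - base_signal_rate)
  p_enriched <- (o0 * enrichment_odds) / (1 + o0 * enrichment_odds)
  with_seed(rng_seed, {
    tables <- list()
    signal_sets <- list()
    for (d in seq_len(n_datasets)) {
      n <- length(universe)
      p_sig <- ifelse(universe %in% enriched_set, p_enriched, base_signal_rate)
      is_sig <- stats::runif(n) < p_sig
      sgn <- switch(signal_direction,
                    both = sample(c(-1, 1), n, replace = TRUE),
                    up = rep(1, n),
                    down = rep(-1, n))
      lfc <- stats::rnorm(n, 0, noise_sd)
      lfc[is_sig] <- sgn[is_sig] *
        (effect_size_log2fc + abs(stats::rnorm(sum(is_sig), 0, noise_sd)))
      adj_p <- stats::runif(n)
      adj_p[is_sig] <- stats::rbeta(sum(is_sig), 0.3, 30)
      id <- sprintf("synthDE%02d", d)
      tables[[id]] <- de_table(
        data.frame(gene_id = universe, log2fc = lfc, adj_p = adj_p,
                   stringsAsFactors = FALSE),
        dataset = id, species = species
      )
      signal_sets[[id]] <- universe[is_sig]
    }
    list(tables = tables,
         truth = list(de_enriched_sets = signal_sets, params = params))
  })
}

#' Write a coherent set of synthetic pipeline inputs to a directory
#'
#' Generates a planted-module network, a curated observation table over
#' genes drawn from the network (module members get directional true
#' effects, so the curated seed set is concentrated in the module), and DE
#' tables enriched for the curated genes, then writes everything in the
#' file formats the readers consume, together with a ready-to-run YAML
#' config and a truth JSON.
#'
#' @param dir Output directory (created if needed).
#' @param n_nodes,module_size,intra_module_edge_boost Network parameters,
#'   see [synth_network()].
#' @param n_extra_genes Curated genes sampled from outside the module.
#' @param n_datasets DE tables to generate, see [synth_de_tables()].
#' @param consistency_rate See [synth_observations()].
#' @param rng_seed Integer master seed (sub-seeds are derived from it).
#' @return Invisibly, a list with the paths written and the ground truth.
#' @export
synth_demo_inputs <- function(dir, n_nodes = 2000L, module_size = 50L,
                              intra_module_edge_boost = 0.3,
                              n_extra_genes = 30L, n_datasets = 6L,
                              consistency_rate = 0.7, rng_seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sn <- synth_network(n_nodes = n_nodes, module_size = module_size,
                      intra_module_edge_boost = intra_module_edge_boost,
                      rng_seed = rng_seed)
  extra <- with_seed(rng_seed + 1L, {
    sample(setdiff(sprintf("NODE%05d", seq_len(n_nodes)),
                   sn$truth$planted_module), n_extra_genes)
  })
  curated <- c(sn$truth$planted_module, extra)
  # module members are the effect-carrying genes; extras mostly no_effect
  effect_mix_module <- c(protective = 0.45, detrimental = 0.45,
                         no_effect = 0.10)
  so <- synth_observations(genes = curated,
                           consistency_rate = consistency_rate,
                           effect_mix = effect_mix_module,
                           rng_seed = rng_seed + 2L)
  universe <- sprintf("NODE%05d", seq_len(n_nodes))
  sd <- synth_de_tables(n_datasets = n_datasets, universe = universe,
                        enriched_set = curated, rng_seed = rng_seed + 3L)

  obs_path <- file.path(dir, "observations.tsv")
  write_tsv(as.data.frame(so$observations), obs_path)
  net_path <- file.path(dir, "network_edges.tsv")
  utils::write.table(sn$edges, net_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  de_paths <- vapply(names(sd$tables), function(id) {
    p <- file.path(dir, paste0(id, ".tsv"))
    write_tsv(as.data.frame(sd$tables[[id]]), p)
    p
  }, "")
  truth <- list(true_gene_effects = as.list(so$truth$true_gene_effects),
                planted_module = sn$truth$planted_module,
                de_enriched_sets = sd$truth$de_enriched_sets,
                rng_seed = rng_seed)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  cfg <- list(observations = obs_path, de_tables = unname(de_paths),
              network = net_path, rng_seed = rng_seed)
  cfg_path <- file.path(dir, "run.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(config = cfg_path, observations = obs_path,
                 network = net_path, de_tables = unname(de_paths),
                 truth = truth, truth_path = truth_path))
}
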