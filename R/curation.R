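# Curation of gene-perturbation observations in animal models of OA:
# reading the observation table, inferring per-experiment gene effects,
# combining them into per-gene consensus labels, and summarising the
# corpus (counts, consistency between studies/approaches/models).

OA_EFFECTS <- c("protective", "detrimental", "no_effect", "mixed")
OA_CONSENSUS <- c("protective", "detrimental", "ambiguous", "no_effect", "mixed")
OA_ACTIVITY <- c("increase", "decrease")
OA_APPROACH <- c("genetic", "exogenous")
OA_MODELS <- c("surgical", "spontaneous", "high_fat_diet", "chemical",
               "mechanical", "genetic_susceptibility", "other")

#' Default curation configuration
#'
#' Term maps used by [read_observations()] to translate the free-text
#' vocabulary of curated perturbation tables into the package's controlled
#' enums. All maps are editable: supply a modified copy to
#' `read_observations(config = )`.
#'
#' The maps are:
#' \describe{
#'   \item{effect_terms}{observed phenotype effect \eqn{\to}
#'     protective / detrimental / no_effect / mixed.}
#'   \item{activity_terms}{the "effect on protein product" vocabulary
#'     (Removal, Inhibition, Overexpression, ...) \eqn{\to} increase / decrease
#'     of protein activity.}
#'   \item{intervention_activity}{fallback mapping intervention \eqn{\to}
#'     activity direction, used when the table carries no activity column
#'     (knockout, siRNA, antibody, inhibitor \eqn{\to} decrease;
#'     overexpression, protein, agonist \eqn{\to} increase).}
#'   \item{intervention_approach}{intervention \eqn{\to} genetic / exogenous.
#'     Genetic interventions form a closed vocabulary; unmapped interventions
#'     (arbitrary drug names) default to exogenous.}
#'   \item{model_terms}{model descriptions \eqn{\to} model category enum.
#'     Matching tries the full string, then the token before the first
#'     separator; unmatched models become "other" with the original text
#'     kept as subtype.}
#'   \item{mirna_patterns}{regular expressions identifying miRNA symbols,
#'     used by [map_to_human()].}
#' }
#'
#' @return A named list of term maps.
#' @export
#' @examples
#' cfg <- curation_config()
#' cfg$activity_terms[["removal"]]
curation_config <- function() {
  list(
    effect_terms = c(
      "protective" = "protective",
      "detrimental" = "detrimental",
      "no effect" = "no_effect",
      "no_effect" = "no_effect",
      "none" = "no_effect",
      "mixed" = "mixed"
    ),
    activity_terms = c(
      "increase" = "increase",
      "decrease" = "decrease",
      "removal" = "decrease",
      "inhibition" = "decrease",
      "deficiency" = "decrease",
      "knockdown" = "decrease",
      "knock-down" = "decrease",
      "overexpression" = "increase",
      "activation" = "increase"
    ),
    intervention_activity = c(
      "knockout" = "decrease",
      "knockdown" = "decrease",
      "knock-down" = "decrease",
      "sirna" = "decrease",
      "shrna" = "decrease",
      "antibody" = "decrease",
      "inhibitor" = "decrease",
      "antagonist" = "decrease",
      "haploinsufficiency" = "decrease",
      "overexpression" = "increase",
      "knockin" = "increase",
      "knock-in" = "increase",
      "protein" = "increase",
      "agonist" = "increase",
      "activator" = "increase"
    ),
    intervention_approach = c(
      "knockout" = "genetic",
      "knockin" = "genetic",
      "knock-in" = "genetic",
      "overexpression" = "genetic",
      "mutation" = "genetic",
      "haploinsufficiency" = "genetic",
      "transgenic" = "genetic"
    ),
    model_terms = c(
      "surgical" = "surgical",
      "spontaneous" = "spontaneous",
      "ageing" = "spontaneous",
      "aging" = "spontaneous",
      "high fat diet" = "high_fat_diet",
      "high-fat diet" = "high_fat_diet",
      "chemical" = "chemical",
      "collagenase" = "chemical",
      "mia" = "chemical",
      "monosodium iodoacetate" = "chemical",
      "mechanical" = "mechanical",
      "treadmill" = "mechanical",
      "injurious load" = "mechanical",
      "str/ort" = "genetic_susceptibility",
      "genetic susceptibility" = "genetic_susceptibility",
      # canonical category names round-trip unchanged
      "high_fat_diet" = "high_fat_diet",
      "genetic_susceptibility" = "genetic_susceptibility",
      "other" = "other"
    ),
    mirna_patterns = c("^MIR[0-9]", "^MIR-", "^MIRLET", "^LET-?7")
  )
}

map_term <- function(x, map, what, allow_na = FALSE) {
  key <- norm_key(x)
  out <- unname(map[key])
  bad <- which(is.na(out) & !(allow_na & (is.na(x) | key == "")))
  list(value = out, bad = bad)
}

# category + free-text subtype from a model description like "Surgical - DMM"
parse_model <- function(x, model_terms) {
  key <- norm_key(x)
  cat <- unname(model_terms[key])
  sub <- rep("", length(x))
  miss <- is.na(cat)
  if (any(miss)) {
    parts <- strsplit(key[miss], "[-−–+]", perl = FALSE)
    head1 <- trimws(vapply(parts, `[`, "", 1L))
    cat2 <- unname(model_terms[head1])
    rest <- vapply(parts, function(p) {
      trimws(paste(p[-1L], collapse = " "))
    }, "")
    cat[miss] <- cat2
    sub[miss] <- rest
    still <- is.na(cat)
    cat[still] <- "other"
    sub[still] <- trimws(x[still])
  }
  data.frame(model = cat, model_subtype = sub, stringsAsFactors = FALSE)
}

#' Read a curated gene-perturbation observation table
#'
#' Parses a CSV/TSV table of gene-perturbation experiments in animal models
#' of osteoarthritis into a validated observation data frame with the
#' canonical columns `gene`, `pmid`, `intervention`, `activity_change`,
#' `approach`, `model`, `model_subtype`, `observed_effect`, `specificity`
#' and `species`. Gene symbols are uppercased and whitespace-trimmed;
#' free-text vocabularies are translated via the term maps in `config`.
#'
#' If the file lacks an `activity_change` column, the direction of the
#' modulation is derived from the intervention via
#' `config$intervention_activity`; similarly a missing `approach` column is
#' derived via `config$intervention_approach` (unmapped interventions are
#' treated as exogenous, since drugs carry arbitrary names while genetic
#' interventions form a closed vocabulary).
#'
#' @param path Path to a delimited text file with a header row. Files ending
#'   in `.csv` are read comma-separated, anything else tab-separated.
#' @param schema Optional named character vector remapping canonical column
#'   names to the file's column names, e.g.
#'   `c(gene = "Humangene", activity_change = "Effect on protein product")`.
#' @param config Term maps, see [curation_config()].
#' @return A `data.frame` of observations (class `oa_observations`), one row
#'   per experiment.
#' @seealso [infer_effect()], [gene_summaries()], [consistency_report()],
#'   [summary_counts()]
#' @export
read_observations <- function(path, schema = NULL, config = curation_config()) {
  if (!file.exists(path)) stop_schema("observation file not found: ", path)
  df <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }

  canon <- c("gene", "pmid", "intervention", "activity_change", "approach",
             "model", "observed_effect", "specificity", "species")
  cols <- stats::setNames(canon, canon)
  if (!is.null(schema)) cols[names(schema)] <- schema

  optional <- c("activity_change", "approach", "specificity", "species")
  for (cn in canon) {
    if (!(cols[[cn]] %in% names(df))) {
      if (cn %in% optional) next
      stop_schema("missing mandatory column: '", cols[[cn]],
                  "' (for field '", cn, "')")
    }
  }
  get_col <- function(cn) {
    if (cols[[cn]] %in% names(df)) as.character(df[[cols[[cn]]]]) else
      rep(NA_character_, nrow(df))
  }

  n <- nrow(df)
  if (n == 0L) {
    out <- data.frame(gene = character(), pmid = character(),
                      intervention = character(), activity_change = character(),
                      approach = character(), model = character(),
                      model_subtype = character(), observed_effect = character(),
                      specificity = character(), species = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("oa_observations", "data.frame")
    return(out)
  }

  gene <- toupper(trimws(get_col("gene")))
  if (any(gene == "" | is.na(gene))) {
    stop_schema("empty gene symbol in row(s): ",
                paste(which(gene == "" | is.na(gene)), collapse = ", "))
  }
  pmid <- trimws(get_col("pmid"))
  intervention <- trimws(get_col("intervention"))

  eff <- map_term(get_col("observed_effect"), config$effect_terms)
  if (length(eff$bad)) {
    stop_schema("unmappable observed_effect value(s) '",
                paste(unique(get_col("observed_effect")[eff$bad]), collapse = "', '"),
                "' in row(s): ", paste(eff$bad, collapse = ", "))
  }

  act_raw <- get_col("activity_change")
  if (all(is.na(act_raw))) {
    act <- unname(config$intervention_activity[norm_key(intervention)])
  } else {
    m <- map_term(act_raw, config$activity_terms)
    act <- m$value
  }
  if (anyNA(act)) {
    stop_schema("cannot determine activity_change in row(s): ",
                paste(which(is.na(act)), collapse = ", "),
                " (unknown term and no intervention mapping)")
  }

  app_raw <- get_col("approach")
  if (all(is.na(app_raw))) {
    app <- unname(config$intervention_approach[norm_key(intervention)])
    app[is.na(app)] <- "exogenous"
  } else {
    app <- norm_key(app_raw)
    bad <- which(!(app %in% OA_APPROACH))
    if (length(bad)) {
      stop_schema("unmappable approach value(s) in row(s): ",
                  paste(bad, collapse = ", "))
    }
  }

  mod <- parse_model(get_col("model"), config$model_terms)

  out <- data.frame(
    gene = gene, pmid = pmid, intervention = intervention,
    activity_change = act, approach = app,
    model = mod$model, model_subtype = mod$model_subtype,
    observed_effect = eff$value,
    specificity = get_col("specificity"),
    species = get_col("species"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("oa_observations", "data.frame")
  out
}

#' Infer the per-experiment gene effect on OA severity
#'
#' Combines the direction of the modulation (increase or decrease of protein
#' activity) with the observed effect on OA joint-damage phenotypes into the
#' inferred role of the gene itself, akin to the oncogene / tumour-suppressor
#' distinction: worse OA after removing a gene implies the gene is
#' protective, while removal of a detrimental gene attenuates damage.
#'
#' The mapping is: (decrease, detrimental) -> protective;
#' (decrease, protective) -> detrimental; (increase, x) -> x for directional
#' x; `no_effect` and `mixed` observations propagate unchanged.
#'
#' @param activity_change Character vector, "increase" or "decrease".
#' @param observed_effect Character vector, one of "protective",
#'   "detrimental", "no_effect", "mixed".
#' @return Character vector of inferred effects, same length as the inputs.
#' @export
#' @examples
#' infer_effect("decrease", "detrimental")  # knockout worsens OA -> protective
#' infer_effect("increase", "protective")   # overexpression helps -> protective
infer_effect <- function(activity_change, observed_effect) {
  if (!all(activity_change %in% OA_ACTIVITY)) {
    stop("activity_change must be one of: ", paste(OA_ACTIVITY, collapse = ", "),
         call. = FALSE)
  }
  if (!all(observed_effect %in% OA_EFFECTS)) {
    stop("observed_effect must be one of: ", paste(OA_EFFECTS, collapse = ", "),
         call. = FALSE)
  }
  n <- max(length(activity_change), length(observed_effect))
  activity_change <- rep_len(activity_change, n)
  observed_effect <- rep_len(observed_effect, n)
  out <- observed_effect
  flip <- activity_change == "decrease" &
    observed_effect %in% c("protective", "detrimental")
  out[flip] <- ifelse(observed_effect[flip] == "protective",
                      "detrimental", "protective")
  out
}

#' Combine per-experiment inferred effects into a consensus label
#'
#' Directional disagreement (both protective and detrimental present) yields
#' "ambiguous"; a single direction wins, with no-effect observations
#' superseded by any directional observation; mixed is returned only when no
#' directional label exists; a gene is "no_effect" only if every observation
#' reported no effect.
#'
#' @param inferred Non-empty character vector of inferred effects
#'   (see [infer_effect()]).
#' @return One of "protective", "detrimental", "ambiguous", "mixed",
#'   "no_effect".
#' @export
#' @examples
#' consensus_effect(c("protective", "protective", "no_effect"))
#' consensus_effect(c("detrimental", "protective"))
consensus_effect <- function(inferred) {
  if (length(inferred) == 0L) stop("empty effect list", call. = FALSE)
  if (!all(inferred %in% OA_EFFECTS)) {
    stop("effects must be one of: ", paste(OA_EFFECTS, collapse = ", "),
         call. = FALSE)
  }
  has_p <- any(inferred == "protective")
  has_d <- any(inferred == "detrimental")
  if (has_p && has_d) return("ambiguous")
  if (has_p) return("protective")
  if (has_d) return("detrimental")
  if (any(inferred == "mixed")) return("mixed")
  "no_effect"
}

#' Per-gene consensus summary of a curated observation table
#'
#' @param observations An observation table from [read_observations()] (or a
#'   data frame with the same canonical columns).
#' @return A data frame with one row per gene: `gene`, `consensus`,
#'   `n_observations`, `n_genetic`, `n_exogenous`, `n_publications` and
#'   `models_studied` (comma-separated model categories).
#' @export
gene_summaries <- function(observations) {
  obs <- as.data.frame(observations)
  if (nrow(obs) == 0L) {
    return(data.frame(gene = character(), consensus = character(),
                      n_observations = integer(), n_genetic = integer(),
                      n_exogenous = integer(), n_publications = integer(),
                      models_studied = character(), stringsAsFactors = FALSE))
  }
  obs$inferred <- infer_effect(obs$activity_change, obs$observed_effect)
  by_gene <- split(obs, obs$gene)
  rows <- lapply(by_gene, function(g) {
    data.frame(
      gene = g$gene[1L],
      consensus = consensus_effect(g$inferred),
      n_observations = nrow(g),
      n_genetic = sum(g$approach == "genetic"),
      n_exogenous = sum(g$approach == "exogenous"),
      n_publications = length(unique(g$pmid)),
      models_studied = paste(sort(unique(g$model)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

# directional inferred effects of one gene's observations; mixed and
# no_effect are ignored for consistency purposes
directional <- function(inferred) inferred[inferred %in% c("protective", "detrimental")]

# TRUE when a set of inferred effects never contains both directions
is_consistent <- function(inferred) {
  d <- directional(inferred)
  !(any(d == "protective") && any(d == "detrimental"))
}

#' Cross-study, cross-approach and cross-model consistency of gene effects
#'
#' Quantifies how reproducible inferred gene effects are across the corpus:
#' \describe{
#'   \item{genetic_multi}{genes with two or more genetic observations whose
#'     inferred effects never contain both protective and detrimental.}
#'   \item{exogenous_multi}{the same for exogenous observations.}
#'   \item{cross_approach}{genes studied by both approaches whose
#'     per-approach consensus labels agree (default), or whose pooled
#'     directional effects never conflict
#'     (`cross_approach_method = "observations"`).}
#'   \item{cross_model}{genes with observations in both spontaneous and
#'     surgical models, unambiguous within each, whose per-model consensus
#'     labels agree.}
#' }
#' Mixed observations carry no direction and are excluded from consistency
#' counting; genes with only no-effect observations count as consistent.
#'
#' @param observations Observation table, see [read_observations()].
#' @param cross_approach_method "consensus" (compare per-approach consensus
#'   labels) or "observations" (pool directional effects across approaches).
#' @return An object of class `oa_consistency`: a list of
#'   `(n_consistent, n_total)` pairs for the four comparisons.
#' @export
consistency_report <- function(observations,
                               cross_approach_method = c("consensus", "observations")) {
  cross_approach_method <- match.arg(cross_approach_method)
  obs <- as.data.frame(observations)
  pair <- function(con, tot) c(n_consistent = con, n_total = tot)
  if (nrow(obs) == 0L) {
    out <- list(genetic_multi = pair(0L, 0L), exogenous_multi = pair(0L, 0L),
                cross_approach = pair(0L, 0L), cross_model = pair(0L, 0L),
                cross_approach_method = cross_approach_method)
    class(out) <- "oa_consistency"
    return(out)
  }
  obs$inferred <- infer_effect(obs$activity_change, obs$observed_effect)

  multi_approach <- function(which_approach) {
    sub <- obs[obs$approach == which_approach, , drop = FALSE]
    eff <- split(sub$inferred, sub$gene)
    eff <- eff[vapply(eff, length, 1L) >= 2L]
    pair(sum(vapply(eff, is_consistent, TRUE)), length(eff))
  }

  by_gene <- split(obs, obs$gene)
  both <- Filter(function(g) {
    any(g$approach == "genetic") && any(g$approach == "exogenous")
  }, by_gene)
  if (cross_approach_method == "consensus") {
    ca_ok <- vapply(both, function(g) {
      cg <- consensus_effect(g$inferred[g$approach == "genetic"])
      ce <- consensus_effect(g$inferred[g$approach == "exogenous"])
      cg == ce
    }, TRUE)
  } else {
    ca_ok <- vapply(both, function(g) is_consistent(g$inferred), TRUE)
  }

  in_both_models <- Filter(function(g) {
    any(g$model == "spontaneous") && any(g$model == "surgical")
  }, by_gene)
  cm <- vapply(in_both_models, function(g) {
    cs <- consensus_effect(g$inferred[g$model == "spontaneous"])
    cu <- consensus_effect(g$inferred[g$model == "surgical"])
    if (cs == "ambiguous" || cu == "ambiguous") return(NA)
    cs == cu
  }, TRUE)
  cm <- cm[!is.na(cm)]

  out <- list(
    genetic_multi = multi_approach("genetic"),
    exogenous_multi = multi_approach("exogenous"),
    cross_approach = pair(sum(ca_ok), length(ca_ok)),
    cross_model = pair(sum(cm), length(cm)),
    cross_approach_method = cross_approach_method
  )
  class(out) <- "oa_consistency"
  out
}

#' @export
print.oa_consistency <- function(x, ...) {
  cat("Consistency of inferred gene effects\n")
  fmt <- function(p, label) {
    rate <- if (p[["n_total"]] > 0) {
      sprintf(" (%.0f%%)", 100 * p[["n_consistent"]] / p[["n_total"]])
    } else ""
    cat(sprintf("  %-28s %d/%d%s\n", label, p[["n_consistent"]],
                p[["n_total"]], rate))
  }
  fmt(x$genetic_multi, "genetic, multiply studied:")
  fmt(x$exogenous_multi, "exogenous, multiply studied:")
  fmt(x$cross_approach, "genetic vs exogenous:")
  fmt(x$cross_model, "spontaneous vs surgical:")
  invisible(x)
}

#' Corpus-level counts for a curated observation table
#'
#' @param observations Observation table, see [read_observations()].
#' @return An object of class `oa_summary_counts`: distinct publications and
#'   genes (overall and per approach), observation counts per approach and
#'   per model category, and distinct publications per gene.
#' @export
summary_counts <- function(observations) {
  obs <- as.data.frame(observations)
  gen <- obs[obs$approach == "genetic", , drop = FALSE]
  exo <- obs[obs$approach == "exogenous", , drop = FALSE]
  per_model <- table(factor(obs$model, levels = OA_MODELS))
  per_gene_pubs <- if (nrow(obs)) {
    vapply(split(obs$pmid, obs$gene), function(p) length(unique(p)), 1L)
  } else {
    stats::setNames(integer(), character())
  }
  out <- list(
    n_publications = length(unique(obs$pmid)),
    n_unique_genes = length(unique(obs$gene)),
    n_genetic_observations = nrow(gen),
    n_genetic_genes = length(unique(gen$gene)),
    n_genetic_publications = length(unique(gen$pmid)),
    n_exogenous_observations = nrow(exo),
    n_exogenous_genes = length(unique(exo$gene)),
    n_exogenous_publications = length(unique(exo$pmid)),
    per_model_counts = as.list(stats::setNames(as.integer(per_model),
                                               names(per_model))),
    per_gene_study_counts = as.list(per_gene_pubs)
  )
  class(out) <- "oa_summary_counts"
  out
}

#' @export
print.oa_summary_counts <- function(x, ...) {
  cat("Curated corpus summary\n")
  cat(sprintf("  publications: %d   unique genes: %d\n",
              x$n_publications, x$n_unique_genes))
  cat(sprintf("  genetic:   %d observations of %d genes (%d publications)\n",
              x$n_genetic_observations, x$n_genetic_genes,
              x$n_genetic_publications))
  cat(sprintf("  exogenous: %d observations of %d genes (%d publications)\n",
              x$n_exogenous_observations, x$n_exogenous_genes,
              x$n_exogenous_publications))
  pm <- unlist(x$per_model_counts)
  pm <- pm[pm > 0]
  if (length(pm)) {
    cat("  per model: ",
        paste(sprintf("%s=%d", names(pm), pm), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
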