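# Differential-expression gene sets and their overlap with the curated OA
# genes: thresholding DE tables, ortholog mapping, Fisher exact overlap
# tests, chi-square effect-class proportion tests, BH correction.

#' Read a differential-expression result table
#'
#' Reads a tab-separated export with one row per gene carrying a fold
#' change and an adjusted p-value, as produced by skeletal transcriptomics
#' repositories. Duplicate gene identifiers are collapsed to the row with
#' the largest absolute log2 fold change.
#'
#' @param path Path to a TSV file with a header.
#' @param gene_col,fc_col,p_col Column names for the gene identifier, fold
#'   change and adjusted p-value.
#' @param fc_scale "log2" (default) if `fc_col` holds log2 fold changes,
#'   "linear" if it holds signed linear fold changes (converted to log2;
#'   negative values are interpreted as -1/x style down-regulation).
#' @param dataset,species,tissue,condition Optional metadata strings stored
#'   as attributes.
#' @return A `de_table`: data frame with columns `gene_id`, `log2fc`,
#'   `adj_p` and metadata attributes.
#' @export
read_de_table <- function(path, gene_col = "gene_id", fc_col = "log2fc",
                          p_col = "adj_p", fc_scale = c("log2", "linear"),
                          dataset = basename(path), species = NA_character_,
                          tissue = NA_character_, condition = NA_character_) {
  fc_scale <- match.arg(fc_scale)
  if (!file.exists(path)) stop_schema("DE table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in c(gene_col, fc_col, p_col)) {
    if (!(cn %in% names(df))) stop_schema("missing column '", cn, "' in ", path)
  }
  de_table(data.frame(gene_id = as.character(df[[gene_col]]),
                      log2fc = as.numeric(df[[fc_col]]),
                      adj_p = as.numeric(df[[p_col]]),
                      stringsAsFactors = FALSE),
           fc_scale = fc_scale, dataset = dataset, species = species,
           tissue = tissue, condition = condition)
}

#' Construct a DE table from a data frame
#'
#' @param df Data frame with columns `gene_id`, `log2fc` (or linear fold
#'   change, see `fc_scale`) and `adj_p`.
#' @inheritParams read_de_table
#' @return A `de_table` data frame.
#' @export
de_table <- function(df, fc_scale = c("log2", "linear"), dataset = "dataset",
                     species = NA_character_, tissue = NA_character_,
                     condition = NA_character_) {
  fc_scale <- match.arg(fc_scale)
  stopifnot(all(c("gene_id", "log2fc", "adj_p") %in% names(df)))
  df <- df[, c("gene_id", "log2fc", "adj_p")]
  if (fc_scale == "linear") {
    fc <- df$log2fc
    lfc <- rep(NA_real_, length(fc))
    neg <- !is.na(fc) & fc < 0
    lfc[neg] <- -log2(-fc[neg])
    lfc[!neg & !is.na(fc)] <- log2(fc[!neg & !is.na(fc)])
    df$log2fc <- lfc
  }
  bad <- !is.na(df$adj_p) & (df$adj_p < 0 | df$adj_p > 1)
  if (any(bad)) stop_schema("adjusted p-values outside [0, 1]")
  # deduplicate: keep the strongest change per gene
  df <- df[order(-abs(df$log2fc)), , drop = FALSE]
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "dataset") <- dataset
  attr(df, "species") <- species
  attr(df, "tissue") <- tissue
  attr(df, "condition") <- condition
  class(df) <- c("de_table", "data.frame")
  df
}

#' Extract significant up/down gene sets from a DE table
#'
#' Applies the standard differential-expression filter: absolute fold change
#' at least `fc_threshold` (linear scale, default 1.5) and adjusted p-value
#' at most `p_threshold` (default 0.05). Both boundaries are inclusive.
#'
#' @param table A `de_table` (see [de_table()]).
#' @param fc_threshold Linear fold-change threshold, must be >= 1.
#' @param p_threshold Adjusted p-value threshold.
#' @return A list of class `de_gene_sets`: `up`, `down` (character vectors
#'   of gene identifiers), `universe` (all measured genes) and `dataset`,
#'   `species` metadata.
#' @export
significant_gene_sets <- function(table, fc_threshold = 1.5, p_threshold = 0.05) {
  if (fc_threshold < 1) {
    stop("fc_threshold is on the linear fold-change scale and must be >= 1",
         call. = FALSE)
  }
  lfc <- log2(fc_threshold)
  ok_p <- !is.na(table$adj_p) & table$adj_p <= p_threshold
  up <- table$gene_id[ok_p & table$log2fc >= lfc]
  down <- table$gene_id[ok_p & table$log2fc <= -lfc]
  structure(list(up = up, down = down, universe = table$gene_id,
                 dataset = attr(table, "dataset") %||% "dataset",
                 species = attr(table, "species") %||% NA_character_),
            class = "de_gene_sets")
}

#' Map gene symbols to human symbols via an ortholog table
#'
#' Maps symbols through a many-to-one ortholog table, drops unmapped symbols
#' (counted in the `n_unmapped` attribute) and removes miRNA identifiers.
#' Without an ortholog map, symbols are uppercased and passed through (the
#' miRNA filter still applies).
#'
#' @param symbols Character vector of gene symbols.
#' @param ortholog_map Optional data frame whose first two columns are the
#'   source symbol and the human symbol.
#' @param mirna_patterns Regular expressions (applied case-insensitively to
#'   the uppercased output) identifying miRNA symbols to remove; `NULL`
#'   disables the filter.
#' @return Character vector of unique human symbols, with attributes
#'   `n_unmapped` and `n_mirna_removed`.
#' @export
#' @examples
#' map_to_human(c("Acan", "Mir140"),
#'              ortholog_map = data.frame(from = c("Acan", "Mir140"),
#'                                        to = c("ACAN", "MIR140")))
map_to_human <- function(symbols, ortholog_map = NULL,
                         mirna_patterns = curation_config()$mirna_patterns) {
  symbols <- symbols[!is.na(symbols) & symbols != ""]
  n_unmapped <- 0L
  if (!is.null(ortholog_map)) {
    from <- trimws(as.character(ortholog_map[[1L]]))
    to <- toupper(trimws(as.character(ortholog_map[[2L]])))
    idx <- match(trimws(symbols), from)
    n_unmapped <- sum(is.na(idx))
    out <- to[idx[!is.na(idx)]]
  } else {
    out <- toupper(trimws(symbols))
  }
  out <- unique(out)
  n_mirna <- 0L
  if (!is.null(mirna_patterns) && length(mirna_patterns)) {
    is_mir <- Reduce(`|`, lapply(mirna_patterns, grepl, x = out, perl = TRUE))
    n_mirna <- sum(is_mir)
    out <- out[!is_mir]
  }
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_mirna_removed") <- n_mirna
  out
}

#' One-sided Fisher exact test for gene-set overlap
#'
#' Tests over-representation of `reference` genes in `query` against a
#' hypergeometric null over `universe`. The one-sided enrichment p-value is
#' the upper hypergeometric tail P(X >= k); the odds ratio is the sample
#' odds ratio of the 2x2 table, with a 0.5 continuity addition to every
#' cell only when some cell is zero.
#'
#' @param query,reference Character vectors of gene identifiers; both must
#'   be subsets of `universe`.
#' @param universe Character vector: all genes that could have appeared.
#' @return A list of class `overlap_test`: `k_overlap`, `n_set` (query
#'   size), `n_reference`, `n_universe`, `odds_ratio`, `p` (`p_adj` is
#'   filled in by callers that correct across a family of tests).
#' @export
fisher_overlap <- function(query, reference, universe) {
  universe <- unique(universe)
  query <- unique(query)
  reference <- unique(reference)
  if (length(universe) < 1L) stop("empty universe", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query contains genes absent from the universe", call. = FALSE)
  }
  if (!all(reference %in% universe)) {
    stop("reference contains genes absent from the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  m <- length(reference)
  k <- length(intersect(query, reference))
  p <- hypergeom_enrichment_p(k, n, m, N)
  a <- k; b <- n - k; c_ <- m - k; d <- N - n - m + k
  if (min(a, b, c_, d) == 0L) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  structure(list(k_overlap = k, n_set = n, n_reference = m, n_universe = N,
                 odds_ratio = or, p = p, p_adj = NA_real_),
            class = "overlap_test")
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' The one-sided Fisher exact enrichment p-value for a 2x2 table with
#' `k` overlapping genes between a set of size `n_set` and a reference of
#' size `n_reference` drawn from a universe of `n_universe` genes.
#' Vectorised over all arguments.
#'
#' @param k,n_set,n_reference,n_universe Integer vectors.
#' @return Numeric vector of p-values.
#' @export
hypergeom_enrichment_p <- function(k, n_set, n_reference, n_universe) {
  # P(X >= k) with X ~ Hypergeometric(white = n_reference,
  #                                   black = n_universe - n_reference,
  #                                   drawn = n_set)
  stats::phyper(k - 1, n_reference, n_universe - n_reference, n_set,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment; output order matches
#' input order and values are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NAs preserved).
#' @return Numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Chi-square test of effect-class proportions in a gene set
#'
#' Tests whether protective and detrimental genes are differentially
#' represented inside a differential-expression gene set: a 2x2 chi-square
#' test of independence (effect class x set membership) without continuity
#' correction, 1 degree of freedom. A zero row or column margin makes the
#' test undefined: the result is flagged untestable with `p = NA`, never
#' silently 1.
#'
#' @param de_set Character vector: the DE gene set.
#' @param protective,detrimental Disjoint character vectors of effect-labelled
#'   genes (the universe of the test is their union).
#' @return List with `chi2`, `p`, `df`, `testable` and the 2x2 `counts`.
#' @export
effect_proportion_test <- function(de_set, protective, detrimental) {
  protective <- unique(protective)
  detrimental <- unique(detrimental)
  if (length(intersect(protective, detrimental))) {
    stop("protective and detrimental sets must be disjoint", call. = FALSE)
  }
  a <- sum(protective %in% de_set)
  b <- length(protective) - a
  c_ <- sum(detrimental %in% de_set)
  d <- length(detrimental) - c_
  counts <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("protective", "detrimental"),
                                   c("in_set", "out_set")))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, df = 1L, testable = FALSE,
                counts = counts))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), df = 1L,
       testable = TRUE, counts = counts)
}

#' Overlap and effect-class composition matrix across DE datasets
#'
#' For every dataset and direction (up / down), counts how many of the
#' overlapping genes carry each consensus effect label and tests whether
#' protective and detrimental genes appear in the set in different
#' proportions ([effect_proportion_test()]). Chi-square p-values are
#' BH-adjusted across all dataset-by-direction cells and flagged at
#' `p_adj <= alpha`.
#'
#' @param datasets List of `de_gene_sets` (see [significant_gene_sets()]).
#'   Gene identifiers must already be human symbols.
#' @param summaries Per-gene consensus table from [gene_summaries()], or a
#'   named character vector gene -> consensus label.
#' @param alpha Significance threshold applied to the adjusted p-values.
#' @param restrict_universe If TRUE (default), effect-labelled genes are
#'   intersected with each dataset's measured universe before testing.
#' @return Data frame with one row per dataset x direction: overlap counts
#'   per consensus class, `chi2`, `p`, `p_adj`, `significant`.
#' @export
overlap_effect_matrix <- function(datasets, summaries, alpha = 0.05,
                                  restrict_universe = TRUE) {
  if (length(datasets) == 0L) stop("need at least one dataset", call. = FALSE)
  lab <- if (is.data.frame(summaries)) {
    stats::setNames(summaries$consensus, summaries$gene)
  } else {
    summaries
  }
  rows <- list()
  for (ds in datasets) {
    for (dir in c("up", "down")) {
      set <- ds[[dir]]
      prot <- names(lab)[lab == "protective"]
      detr <- names(lab)[lab == "detrimental"]
      ambi <- names(lab)[lab == "ambiguous"]
      noef <- names(lab)[lab == "no_effect"]
      if (restrict_universe) {
        prot <- intersect(prot, ds$universe)
        detr <- intersect(detr, ds$universe)
        ambi <- intersect(ambi, ds$universe)
        noef <- intersect(noef, ds$universe)
      }
      tst <- effect_proportion_test(set, prot, detr)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds$dataset, direction = dir,
        n_set = length(set),
        n_protective = sum(prot %in% set),
        n_detrimental = sum(detr %in% set),
        n_ambiguous = sum(ambi %in% set),
        n_no_effect = sum(noef %in% set),
        chi2 = tst$chi2, p = tst$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Fisher overlap tests of DE gene sets against a reference gene set
#'
#' Convenience wrapper running [fisher_overlap()] for every dataset and
#' direction against one reference set (typically the effect-labelled OA
#' genes), BH-adjusting across all tests in the run.
#'
#' @inheritParams overlap_effect_matrix
#' @param reference Character vector of reference genes.
#' @param universe "per_dataset" (each dataset's measured genes; reference
#'   intersected with it) or a character vector used as a global universe.
#' @return Data frame with one row per dataset x direction.
#' @export
overlap_tests <- function(datasets, reference, universe = "per_dataset") {
  rows <- list()
  for (ds in datasets) {
    for (dir in c("up", "down")) {
      if (identical(universe, "per_dataset")) {
        uni <- ds$universe
        ref <- intersect(reference, uni)
        qry <- intersect(ds[[dir]], uni)
      } else {
        uni <- universe
        ref <- intersect(reference, uni)
        qry <- intersect(ds[[dir]], uni)
      }
      ft <- fisher_overlap(qry, ref, uni)
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = ds$dataset, direction = dir,
        k_overlap = ft$k_overlap, n_set = ft$n_set,
        n_reference = ft$n_reference, n_universe = ft$n_universe,
        odds_ratio = ft$odds_ratio, p = ft$p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
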