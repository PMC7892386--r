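# Network diffusion with restart over a protein-protein interaction
# network: building the network, propagating seed mass, ranking genes,
# cross-validated recovery of held-out seeds, and candidate prioritisation.

#' Build a gene network from an edge list
#'
#' Constructs an undirected simple graph over uppercased gene symbols:
#' self-loops and duplicate edges are removed and only the largest connected
#' component is retained (ties between equally large components broken by
#' the lexicographically smallest node label). Removal counts are stored on
#' the returned object.
#'
#' @param edges Two-column data frame (or matrix) of gene symbol pairs; any
#'   extra columns (e.g. interaction confidence) are ignored with a warning.
#' @return Object of class `gene_network`: list with the `igraph` graph,
#'   `nodes`, and counts of removed self-loops, duplicate edges and nodes
#'   dropped outside the largest component.
#' @export
build_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop("empty edge list", call. = FALSE)
  if (ncol(edges) > 2L) {
    warning("edge list has more than two columns; extras ignored")
    edges <- edges[, 1:2]
  }
  a <- toupper(trimws(as.character(edges[[1L]])))
  b <- toupper(trimws(as.character(edges[[2L]])))
  keep <- a != b
  n_self <- sum(!keep)
  a <- a[keep]; b <- b[keep]
  # canonical order so (A,B) and (B,A) collapse
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  lo <- lo[!dup]; hi <- hi[!dup]
  if (length(lo) == 0L) stop("no edges left after removing self-loops",
                             call. = FALSE)
  g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  big <- which(sizes == max(sizes))
  if (length(big) > 1L) {
    # tie: keep the component containing the smallest node label
    firsts <- vapply(big, function(ci) {
      min(igraph::V(g)$name[comp$membership == ci])
    }, "")
    big <- big[order(firsts)[1L]]
  }
  keep_v <- igraph::V(g)$name[comp$membership == big]
  n_dropped <- igraph::vcount(g) - length(keep_v)
  g <- igraph::induced_subgraph(g, keep_v)
  structure(list(graph = g,
                 nodes = sort(igraph::V(g)$name),
                 n_self_removed = n_self,
                 n_dup_removed = n_dup,
                 n_nodes_dropped = n_dropped),
            class = "gene_network")
}

#' Read a network edge list file
#'
#' @param path Whitespace- or tab-delimited two-column edge list of gene
#'   symbols (no header, or a header detected by non-symbol-like content is
#'   kept as data; supply clean files). An optional third column is ignored
#'   with a warning.
#' @return A `gene_network`, see [build_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop_schema("network file not found: ", path)
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  build_network(df)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  cat(sprintf("  removed: %d self-loops, %d duplicate edges, %d nodes outside LCC\n",
              x$n_self_removed, x$n_dup_removed, x$n_nodes_dropped))
  invisible(x)
}

# column-normalised (random-walk) adjacency as a sparse matrix;
# node order fixed to network$nodes
transition_matrix <- function(network) {
  A <- igraph::as_adjacency_matrix(network$graph, sparse = TRUE)
  A <- A[network$nodes, network$nodes]
  deg <- Matrix::colSums(A)
  A %*% Matrix::Diagonal(x = 1 / deg)
}

#' Network diffusion with restart from a seed set
#'
#' Propagates probability mass from a set of seed genes over the network by
#' the random-walk-with-restart fixed point
#' \deqn{F = (1 - r) W F + r F_0}
#' where `W` is the column-normalised adjacency matrix, `F0` the uniform
#' distribution over the seeds, and `r` the restart probability. Because
#' `W` is column-stochastic the scores form a probability distribution
#' (non-negative, summing to 1) at every iteration. Nodes are scored by
#' their proximity to the seed set.
#'
#' @param network A `gene_network` from [build_network()].
#' @param seeds Character vector of seed genes; genes absent from the
#'   network are dropped, and an error is raised if none remain.
#' @param r Restart probability in (0, 1].
#' @param tol L1 convergence tolerance on the score change per iteration.
#' @param max_iter Iteration cap; non-convergence sets `converged = FALSE`
#'   with a warning.
#' @param method "iterative" power iteration (default) or "exact" sparse
#'   linear solve of `(I - (1-r) W) F = r F0`.
#' @return Object of class `diffusion_scores`: named score vector
#'   (`scores`), the seeds used, `r`, `iterations`, `residual`, `converged`.
#' @export
diffuse <- function(network, seeds, r = 0.3, tol = 1e-8, max_iter = 1000L,
                    method = c("iterative", "exact")) {
  method <- match.arg(method)
  if (!(r > 0 && r <= 1)) stop("restart probability r must be in (0, 1]",
                               call. = FALSE)
  nodes <- network$nodes
  seeds <- unique(toupper(seeds))
  seeds <- seeds[seeds %in% nodes]
  if (length(seeds) == 0L) {
    stop("seed set is disjoint from the network", call. = FALSE)
  }
  n <- length(nodes)
  f0 <- numeric(n)
  f0[match(seeds, nodes)] <- 1 / length(seeds)
  W <- transition_matrix(network)

  if (method == "exact" || r == 1) {
    if (r == 1) {
      f <- f0
      it <- 0L
      res <- 0
      conv <- TRUE
    } else {
      M <- Matrix::Diagonal(n) - (1 - r) * W
      f <- as.numeric(Matrix::solve(M, r * f0))
      it <- 0L
      res <- sum(abs((1 - r) * as.numeric(W %*% f) + r * f0 - f))
      conv <- TRUE
    }
  } else {
    f <- f0
    it <- 0L
    res <- Inf
    conv <- FALSE
    while (it < max_iter) {
      it <- it + 1L
      f_new <- (1 - r) * as.numeric(W %*% f) + r * f0
      res <- sum(abs(f_new - f))
      f <- f_new
      if (res <= tol) {
        conv <- TRUE
        break
      }
    }
    if (!conv) warning("diffusion did not converge within max_iter")
  }
  structure(list(scores = stats::setNames(f, nodes), seeds = seeds, r = r,
                 iterations = it, residual = res, converged = conv),
            class = "diffusion_scores")
}

#' @export
print.diffusion_scores <- function(x, ...) {
  cat(sprintf("Diffusion scores over %d nodes (%d seeds, r = %.2f)\n",
              length(x$scores), length(x$seeds), x$r))
  cat(sprintf("  %d iterations, L1 residual %.2e, converged: %s\n",
              x$iterations, x$residual, x$converged))
  top <- sort(x$scores, decreasing = TRUE)[seq_len(min(5, length(x$scores)))]
  cat("  top: ", paste(sprintf("%s=%.3g", names(top), top), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Rank genes by diffusion score
#'
#' Ranks genes by descending score (1 = closest to the seeds), ties
#' receiving their average rank. When `exclude` is given (normally the seed
#' set itself), those genes are removed from the ranking domain so that
#' candidates compete only with other non-seed genes.
#'
#' @param scores A `diffusion_scores` object or a named numeric vector.
#' @param exclude Optional character vector of genes to omit.
#' @return Named numeric vector of ranks.
#' @export
rank_genes <- function(scores, exclude = NULL) {
  s <- if (inherits(scores, "diffusion_scores")) scores$scores else scores
  if (!is.null(exclude)) s <- s[!(names(s) %in% exclude)]
  rank(-s, ties.method = "average")
}

#' Cross-validated recovery of held-out seed genes
#'
#' Estimates how well network diffusion recovers known genes: the seeds are
#' split into `k` folds (`repeats` times, independently); for every fold,
#' diffusion is run from the retained seeds and the ranks of the held-out
#' seeds — and of the never-labelled nodes — are recorded among all nodes
#' that are not retained seeds. Pooled rank distributions across all
#' repeats and folds are returned. A held-out gene recovered well ranks far
#' ahead of the unlabelled background.
#'
#' @inheritParams diffuse
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent fold assignments.
#' @param rng_seed Integer seed; identical seeds give identical results.
#' @param design "kfold" (default: `repeats` independent k-fold partitions)
#'   or "holdout" (`repeats * k` random holdouts of `1/k` of the seeds).
#' @param rank_among "non_retained" (held-out genes compete with unlabelled
#'   genes and each other; default) or "unlabelled" (ranking domain limited
#'   to unlabelled nodes plus the gene being ranked).
#' @return Object of class `cv_result`: `heldout_ranks`, `unlabelled_ranks`
#'   (pooled), `n_nodes`, `k`, `repeats`, `rng_seed`, and per-fold sizes.
#' @export
cross_validate <- function(network, seeds, k = 5L, repeats = 100L, r = 0.3,
                           tol = 1e-8, max_iter = 1000L, rng_seed = 1L,
                           design = c("kfold", "holdout"),
                           rank_among = c("non_retained", "unlabelled")) {
  design <- match.arg(design)
  rank_among <- match.arg(rank_among)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  seeds <- unique(toupper(seeds))
  seeds <- seeds[seeds %in% network$nodes]
  if (length(seeds) < k) stop("need at least k seeds in the network",
                              call. = FALSE)
  nodes <- network$nodes
  unlabelled <- setdiff(nodes, seeds)

  folds_list <- with_seed(rng_seed, {
    lapply(seq_len(repeats), function(rep_i) {
      if (design == "kfold") {
        idx <- sample(rep_len(seq_len(k), length(seeds)))
        split(seeds, idx)
      } else {
        m <- max(1L, round(length(seeds) / k))
        lapply(seq_len(k), function(j) sample(seeds, m))
      }
    })
  })

  heldout_ranks <- list()
  unlabelled_ranks <- list()
  heldout_fold <- list()
  unlabelled_fold <- list()
  fold_counter <- 0L
  for (rep_i in seq_len(repeats)) {
    for (fold in folds_list[[rep_i]]) {
      fold_counter <- fold_counter + 1L
      retained <- setdiff(seeds, fold)
      sc <- diffuse(network, retained, r = r, tol = tol,
                    max_iter = max_iter)$scores
      if (rank_among == "non_retained") {
        rk <- rank_genes(sc, exclude = retained)
        heldout_ranks[[length(heldout_ranks) + 1L]] <- rk[fold]
        unlabelled_ranks[[length(unlabelled_ranks) + 1L]] <- rk[unlabelled]
      } else {
        base <- sc[unlabelled]
        heldout_ranks[[length(heldout_ranks) + 1L]] <- vapply(fold, function(g) {
          rank(-c(sc[g], base), ties.method = "average")[1L]
        }, 1)
        unlabelled_ranks[[length(unlabelled_ranks) + 1L]] <-
          stats::setNames(rank(-base, ties.method = "average"), unlabelled)
      }
      heldout_fold[[fold_counter]] <-
        rep(fold_counter, length(heldout_ranks[[fold_counter]]))
      unlabelled_fold[[fold_counter]] <-
        rep(fold_counter, length(unlabelled_ranks[[fold_counter]]))
    }
  }
  heldout_ranks <- unlist(heldout_ranks)
  unlabelled_ranks <- unlist(unlabelled_ranks)
  structure(list(heldout_ranks = unname(heldout_ranks),
                 unlabelled_ranks = unname(unlabelled_ranks),
                 heldout_genes = names(heldout_ranks),
                 unlabelled_genes = names(unlabelled_ranks),
                 heldout_fold = unlist(heldout_fold),
                 unlabelled_fold = unlist(unlabelled_fold),
                 n_nodes = length(nodes), n_seeds = length(seeds),
                 k = k, repeats = repeats, rng_seed = rng_seed,
                 design = design, rank_among = rank_among, r = r),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated seed recovery (%d seeds, %d-fold x %d repeats, r = %.2f)\n",
              x$n_seeds, x$k, x$repeats, x$r))
  cat(sprintf("  median held-out rank:   %.1f / %d\n",
              stats::median(x$heldout_ranks), x$n_nodes))
  cat(sprintf("  median unlabelled rank: %.1f / %d\n",
              stats::median(x$unlabelled_ranks), x$n_nodes))
  invisible(x)
}

#' Test the separation between held-out and unlabelled rank distributions
#'
#' Ranks recorded within one cross-validation fold come from a single
#' diffusion run, and the same held-out genes recur across folds, so
#' pooling all ranks into one two-sample test overstates the effective
#' sample size enormously and its null p-value is badly anti-conservative.
#' The independent sampling unit is the gene: this test averages each
#' gene's rank over all folds in which it appears and runs a one-sided
#' Mann-Whitney test of the held-out genes' mean ranks against the
#' unlabelled genes' mean ranks (alternative: held-out genes rank better).
#'
#' @param cv A `cv_result` from [cross_validate()].
#' @return List with `p`, gene counts on both sides, and the medians of
#'   the per-gene mean ranks.
#' @export
cv_separation_test <- function(cv) {
  h <- tapply(cv$heldout_ranks, cv$heldout_genes, mean)
  u <- tapply(cv$unlabelled_ranks, cv$unlabelled_genes, mean)
  wt <- suppressWarnings(stats::wilcox.test(h, u, alternative = "less"))
  list(p = unname(wt$p.value),
       n_heldout_genes = length(h), n_unlabelled_genes = length(u),
       median_heldout_gene_rank = unname(stats::median(h)),
       median_unlabelled_gene_rank = unname(stats::median(u)))
}

#' Significance of observed gene ranks against the random expectation
#'
#' Tests whether a set of observed network ranks is better (smaller) than
#' expected by chance. The default is a one-sided Wilcoxon signed-rank test
#' of the ranks against the null median `(n_candidates + 1) / 2`, exact for
#' 25 or fewer non-zero differences and a normal approximation above.
#' Observations exactly at the null median carry no information and are
#' dropped; if none remain the test is undefined and an error is raised.
#' A rank-sum flavour (observed ranks vs the full rank population) is
#' available via `flavour = "rank_sum"`.
#'
#' @param observed_ranks Numeric vector of ranks in `[1, n_candidates]`.
#' @param n_candidates Size of the ranking domain.
#' @param flavour "signed_rank" (default) or "rank_sum".
#' @return List with `p`, `statistic`, `n_used`, `null_median`, `flavour`.
#' @export
rank_significance <- function(observed_ranks, n_candidates,
                              flavour = c("signed_rank", "rank_sum")) {
  flavour <- match.arg(flavour)
  if (length(observed_ranks) == 0L) stop("no observed ranks", call. = FALSE)
  if (any(observed_ranks < 1 | observed_ranks > n_candidates)) {
    stop("ranks must lie in [1, n_candidates]", call. = FALSE)
  }
  null_median <- (n_candidates + 1) / 2
  if (flavour == "signed_rank") {
    d <- observed_ranks - null_median
    d <- d[d != 0]
    if (length(d) == 0L) {
      stop("all ranks equal the null median; signed-rank test undefined",
           call. = FALSE)
    }
    exact <- length(d) <= 25 && !any(duplicated(abs(d)))
    wt <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = "less", exact = exact)
    )
    list(p = unname(wt$p.value), statistic = unname(wt$statistic),
         n_used = length(d), null_median = null_median, flavour = flavour)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(observed_ranks, seq_len(n_candidates),
                         alternative = "less")
    )
    list(p = unname(wt$p.value), statistic = unname(wt$statistic),
         n_used = length(observed_ranks), null_median = null_median,
         flavour = flavour)
  }
}

#' Count direct network neighbours that are known OA genes
#'
#' @param network A `gene_network`.
#' @param genes Character vector of genes to query; every gene must be in
#'   the network.
#' @param oa_genes Character vector of effect-labelled OA genes.
#' @return Named integer vector: per queried gene, the number of its direct
#'   neighbours in `oa_genes`.
#' @export
count_oa_interactions <- function(network, genes, oa_genes) {
  genes <- toupper(genes)
  absent <- setdiff(genes, network$nodes)
  if (length(absent)) {
    stop("gene(s) absent from the network: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  oa_genes <- intersect(toupper(oa_genes), network$nodes)
  vapply(genes, function(g) {
    nb <- igraph::neighbors(network$graph, g)$name
    sum(nb %in% oa_genes)
  }, 1L)
}

#' Prioritise candidate genes from network ranks and orthogonal evidence
#'
#' Filters the network ranking to candidates with independent support:
#' differential expression in at least `min_de` human OA datasets, at least
#' `min_interactions` direct interactions with known OA genes, and not
#' already a known OA gene. Retained candidates are sorted by ascending
#' network rank.
#'
#' @param ranks Named numeric vector of network ranks (see [rank_genes()]).
#' @param de_counts Named integer vector: per gene, the number of human DE
#'   datasets in which it is differentially expressed (missing genes count 0).
#' @param interaction_counts Named integer vector: per gene, direct
#'   interactions with known OA genes (see [count_oa_interactions()];
#'   missing genes count 0).
#' @param known Character vector of known (already labelled) OA genes.
#' @param min_de,min_interactions Filter thresholds (defaults 3 and 4).
#' @param tractability Optional named character vector of drug-tractability
#'   labels, passed through to the output.
#' @return Data frame of candidate records sorted by `network_rank`: `gene`,
#'   `network_rank`, `n_oa_interactions`, `n_human_de_datasets`, `known`,
#'   `tractability`.
#' @export
prioritise <- function(ranks, de_counts, interaction_counts, known,
                       min_de = 3L, min_interactions = 4L,
                       tractability = NULL) {
  genes <- names(ranks)
  dc <- ifelse(genes %in% names(de_counts), de_counts[genes], 0L)
  ic <- ifelse(genes %in% names(interaction_counts),
               interaction_counts[genes], 0L)
  kn <- genes %in% known
  out <- data.frame(
    gene = genes,
    network_rank = unname(ranks),
    n_oa_interactions = as.integer(unname(ic)),
    n_human_de_datasets = as.integer(unname(dc)),
    known = kn,
    tractability = if (is.null(tractability)) NA_character_ else
      as.character(tractability[genes]),
    stringsAsFactors = FALSE
  )
  out <- out[out$n_human_de_datasets >= min_de &
               out$n_oa_interactions >= min_interactions &
               !out$known, , drop = FALSE]
  out <- out[order(out$network_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
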