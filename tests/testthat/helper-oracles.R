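# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately written from first principles (textbook
# formulae, exhaustive enumeration, dense linear algebra) so they share no
# code with the implementation paths they check.

# textbook step-up BH: sort ascending, adj_(i) = min over j >= i of m/j p_(j)
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m / i * p[ord[i]])
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# upper hypergeometric tail by explicit choose() summation
hyper_tail_oracle <- function(k, n_set, n_ref, N) {
  jmax <- min(n_set, n_ref)
  if (k > jmax) return(0)
  j <- max(k, 0):jmax
  sum(exp(lchoose(n_ref, j) + lchoose(N - n_ref, n_set - j) -
            lchoose(N, n_set)))
}

# closed-form 2x2 chi-square without continuity correction
chi2_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact one-sided signed-rank p by enumerating all sign vectors:
# V = sum of ranks of |d| with positive sign; p = P(V_null <= V_obs)
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  mean(v_all <= v_obs)
}

# dense random-walk-with-restart solve, written independently of diffuse()
rwr_oracle <- function(edge_df, seeds, r) {
  nodes <- sort(unique(c(edge_df[[1]], edge_df[[2]])))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edge_df))) {
    A[edge_df[[1]][i], edge_df[[2]][i]] <- 1
    A[edge_df[[2]][i], edge_df[[1]][i]] <- 1
  }
  W <- sweep(A, 2, colSums(A), "/")
  f0 <- numeric(n)
  names(f0) <- nodes
  f0[seeds] <- 1 / length(seeds)
  drop(solve(diag(n) - (1 - r) * W, r * f0))
}

# random connected simple graph as an edge data frame (<= n nodes)
random_connected_edges <- function(n, p = 0.15) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    if (length(keep) >= 3) {
      g <- igraph::induced_subgraph(g, keep)
      el <- igraph::as_edgelist(g)
      return(data.frame(from = paste0("N", el[, 1]),
                        to = paste0("N", el[, 2]),
                        stringsAsFactors = FALSE))
    }
  }
}

# quick observation-table builder for curation tests
make_obs <- function(gene, approach = "genetic", activity = "decrease",
                     observed = "detrimental", model = "surgical",
                     pmid = NULL) {
  n <- max(length(gene), length(approach), length(activity),
           length(observed), length(model))
  df <- data.frame(
    gene = rep_len(gene, n),
    pmid = if (is.null(pmid)) sprintf("P%03d", seq_len(n)) else
      rep_len(pmid, n),
    intervention = "Knockout",
    activity_change = rep_len(activity, n),
    approach = rep_len(approach, n),
    model = rep_len(model, n),
    model_subtype = "",
    observed_effect = rep_len(observed, n),
    specificity = "Global",
    species = "Mouse",
    stringsAsFactors = FALSE
  )
  class(df) <- c("oa_observations", "data.frame")
  df
}

# hand-built DE gene-set object
make_sets <- function(id, up, down, universe, species = "human") {
  structure(list(up = up, down = down, universe = universe,
                 dataset = id, species = species),
            class = "de_gene_sets")
}
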