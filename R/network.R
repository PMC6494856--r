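## Sample-correlation network: Pearson correlation matrix, homophily and
## heterophily scores, weighted graph construction, leading-eigenvector
## community detection with a stratified Monte-Carlo modularity null,
## module-factor association, classification rate, eigenvector centrality.

#' Sample-sample Pearson correlation matrix
#'
#' Correlation between the OTU abundance vectors of every pair of samples;
#' the similarity underlying the whole network stage.
#'
#' @param x `coral_norm` or samples x OTUs abundance matrix (>= 2 OTUs).
#' @return object of class `coral_network` with elements `ids` and `r`
#'   (symmetric correlation matrix, unit diagonal).
#' @export
sample_correlation <- function(x) {
  m <- abundance_matrix(x)
  if (ncol(m) < 2) stop("need >= 2 OTUs to correlate samples")
  v <- apply(m, 1, var)
  if (any(v == 0))
    stop("constant abundance vector for sample: ",
         paste(rownames(m)[v == 0], collapse = ", "))
  r <- cor(t(m))
  structure(list(ids = rownames(m), r = r), class = "coral_network")
}

#' @export
print.coral_network <- function(x, ...) {
  cat("coral_network:", length(x$ids), "samples")
  if (!is.null(x$w))
    cat(";", sum(x$w[upper.tri(x$w)] > 0), "edges (policy:",
        attr(x, "negative_policy"), ")")
  cat("\n")
  invisible(x)
}

#' Homophily and heterophily scores
#'
#' Homophily of a factor is the mean correlation over unordered sample pairs
#' sharing a level; heterophily is the mean over pairs with different
#' levels.  Self-pairs are excluded.
#'
#' @param r correlation matrix (or `coral_network`).
#' @param labels factor of level labels, one per sample.
#' @return named list with `homophily`, `heterophily`, and pair counts
#'   `n_within`, `n_between`.  Levels with a single sample contribute no
#'   within pairs (warning); a single-level factor yields `NaN` heterophily
#'   with a warning.
#' @export
homophily <- function(r, labels) {
  if (inherits(r, "coral_network")) r <- r$r
  labels <- as.factor(labels)
  if (length(labels) != nrow(r)) stop("labels must have one entry per sample")
  singletons <- names(which(table(labels) == 1))
  if (length(singletons))
    warning("level(s) with a single sample contribute no within pairs: ",
            paste(singletons, collapse = ", "))
  ut <- upper.tri(r)
  same <- outer(labels, labels, "==") & ut
  diff <- outer(labels, labels, "!=") & ut
  if (!any(diff)) warning("single level: heterophily undefined")
  list(homophily = mean(r[same]), heterophily = mean(r[diff]),
       n_within = sum(same), n_between = sum(diff))
}

#' Homophily/heterophily scores for several design factors
#'
#' @param r correlation matrix or `coral_network`.
#' @param metadata `coral_metadata` (or data.frame of factors).
#' @param factors factor column names to score.
#' @return data.frame with columns `factor`, `homophily`, `heterophily`.
#' @export
homophily_scores <- function(r, metadata,
                             factors = c("genus", "site", "time")) {
  if (inherits(r, "coral_network")) r <- r$r
  samples <- if (inherits(metadata, "coral_metadata")) metadata$samples else metadata
  samples <- samples[rownames(r), , drop = FALSE]
  rows <- lapply(factors, function(f) {
    h <- homophily(r, samples[[f]])
    data.frame(factor = f, homophily = h$homophily,
               heterophily = h$heterophily, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the weighted undirected graph from correlations
#'
#' Modularity and eigenvector centrality are defined for non-negative
#' weights, so negative correlations must be mapped into edge weights by a
#' declared policy: `"truncate"` (default) clamps them to zero,
#' `"shift"` maps r to (r+1)/2, `"absolute"` takes |r|.  An edge exists
#' wherever the resulting weight is positive; the diagonal is zeroed.
#'
#' @param net `coral_network` (from [sample_correlation()]) or a correlation
#'   matrix.
#' @param negative_policy `"truncate"`, `"shift"`, or `"absolute"`.
#' @return `coral_network` with added `w` (weight matrix) and `graph`
#'   (igraph weighted undirected graph); policy stored as an attribute.
#' @export
build_graph <- function(net, negative_policy = c("truncate", "shift", "absolute")) {
  negative_policy <- match.arg(negative_policy)
  if (!inherits(net, "coral_network"))
    net <- structure(list(ids = rownames(net), r = net), class = "coral_network")
  w <- switch(negative_policy,
              truncate = pmax(net$r, 0),
              shift    = (net$r + 1) / 2,
              absolute = abs(net$r))
  diag(w) <- 0
  net$w <- w
  net$graph <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                                   weighted = TRUE, diag = FALSE)
  attr(net, "negative_policy") <- negative_policy
  net
}

## Weight matrix from whatever the caller passes.
weight_matrix <- function(x) {
  if (inherits(x, "coral_network")) {
    if (is.null(x$w)) stop("network has no weights; call build_graph() first")
    x$w
  } else if (igraph::is_igraph(x)) {
    as.matrix(igraph::as_adjacency_matrix(x, attr = "weight", sparse = TRUE))
  } else if (is.matrix(x)) x
  else stop("expected coral_network, igraph graph, or weight matrix")
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) sum_ij (w_ij - k_i k_j / 2m) delta(c_i, c_j)` with weighted
#' degrees k and total edge weight m.
#'
#' @param x `coral_network`, igraph graph, or non-negative weight matrix.
#' @param membership module assignment, one id per node.
#' @return modularity Q.
#' @export
modularity_q <- function(x, membership) {
  w <- weight_matrix(x)
  if (length(membership) != nrow(w)) stop("membership must cover every node")
  if (anyNA(membership)) stop("node missing from partition")
  k <- colSums(w)
  m2 <- sum(w)
  if (m2 == 0) stop("empty graph (no edge weight)")
  q <- 0
  for (mod in unique(membership)) {
    idx <- membership == mod
    q <- q + sum(w[idx, idx]) - sum(k[idx])^2 / m2
  }
  q / m2
}

#' Leading-eigenvector community detection
#'
#' Newman spectral bisection on the weighted modularity matrix
#' `B_ij = w_ij - k_i k_j / 2m`: each candidate community is split by the
#' sign pattern of the leading eigenvector of its generalized modularity
#' matrix, recursively, and a split is kept only when it increases the
#' global modularity Q.  Disconnected components are treated as initial
#' communities.  Module ids are canonicalized by decreasing module size
#' (ties by first sample) for reproducible output.
#'
#' @param x `coral_network` (with weights), igraph graph, or weight matrix.
#' @return object of class `coral_modules`: list with `membership` (named
#'   integer vector), `modularity`, `n_modules`.
#' @export
leading_eigenvector_communities <- function(x) {
  w <- weight_matrix(x)
  n <- nrow(w)
  if (n == 0) stop("empty graph")
  ids <- rownames(w) %||% as.character(seq_len(n))
  k <- colSums(w)
  m2 <- sum(w)
  if (m2 == 0) stop("empty graph (no edge weight)")
  B <- w - outer(k, k) / m2

  ## start from connected components
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  membership <- igraph::components(g)$membership
  q_now <- modularity_q(w, membership)

  queue <- unique(membership)
  next_id <- max(membership) + 1L
  while (length(queue)) {
    mod <- queue[1]; queue <- queue[-1]
    idx <- which(membership == mod)
    if (length(idx) < 2) next
    Bg <- B[idx, idx, drop = FALSE]
    Bg <- Bg - diag(rowSums(Bg))          # generalized modularity matrix
    ev <- eigen(Bg, symmetric = TRUE)
    lead <- ev$vectors[, 1]
    if (ev$values[1] <= 1e-12) next       # no positive split available
    side <- lead >= 0
    if (all(side) || !any(side)) next
    cand <- membership
    cand[idx[!side]] <- next_id
    q_cand <- modularity_q(w, cand)
    if (q_cand > q_now + 1e-12) {
      membership <- cand
      q_now <- q_cand
      queue <- c(queue, mod, next_id)
      next_id <- next_id + 1L
    }
  }

  ## canonical ids: decreasing size, ties by first appearance
  tab <- table(membership)
  ord <- order(-as.vector(tab), vapply(names(tab), function(m)
    min(which(membership == as.numeric(m))), numeric(1)))
  relabel <- setNames(seq_along(ord), names(tab)[ord])
  membership <- setNames(as.integer(relabel[as.character(membership)]), ids)
  structure(list(membership = membership,
                 modularity = q_now,
                 n_modules = length(unique(membership))),
            class = "coral_modules")
}

#' @export
print.coral_modules <- function(x, ...) {
  cat("coral_modules:", x$n_modules, "modules, Q =", signif(x$modularity, 4), "\n")
  print(table(module = x$membership))
  invisible(x)
}

## Stratified shuffle of a correlation matrix: within each stratum (rows
## sharing a host label), the off-diagonal values of those rows are permuted
## among their positions; the matrix is then re-symmetrized by averaging the
## two shuffled copies of each pair.  Exported internals for testability of
## the permutation invariant.
shuffle_correlations <- function(r, strata, per_sample = FALSE, symmetrize = TRUE) {
  n <- nrow(r)
  out <- r
  if (per_sample) {
    for (u in seq_len(n)) {
      j <- setdiff(seq_len(n), u)
      out[u, j] <- r[u, j][sample.int(length(j))]
    }
  } else {
    strata <- as.factor(strata)
    for (s in levels(strata)) {
      rows <- which(strata == s)
      pos <- cbind(rep(rows, each = n), rep(seq_len(n), length(rows)))
      pos <- pos[pos[, 1] != pos[, 2], , drop = FALSE]
      vals <- r[pos]
      out[pos] <- vals[sample.int(length(vals))]
    }
  }
  if (symmetrize) {
    out <- (out + t(out)) / 2
    diag(out) <- 1
  }
  out
}

#' Monte-Carlo modularity significance under a stratified null
#'
#' Generates random networks by shuffling the correlation values within each
#' host stratum (re-symmetrizing by averaging), rebuilding the graph with
#' the same negative-weight policy, re-detecting communities, and recording
#' the null modularity.  The p-value is the proportion of random networks
#' whose modularity meets or exceeds the observed one.
#'
#' @param net `coral_network` with weights (from [build_graph()]).
#' @param host_labels factor defining the strata (host genus by default
#'   usage), one per sample.
#' @param permutations number of random networks (default 999).
#' @param seed optional integer seed.
#' @param per_sample if `TRUE`, shuffle each sample's row individually
#'   instead of pooling within host strata.
#' @return list with `q_obs`, `q_null` (vector), `p_value`, `n_modules_obs`.
#' @export
modularity_null <- function(net, host_labels, permutations = 999, seed = NULL,
                            per_sample = FALSE) {
  if (permutations < 1) stop("permutations must be >= 1")
  policy <- attr(net, "negative_policy") %||% "truncate"
  obs <- leading_eigenvector_communities(net)
  q_null <- numeric(permutations)
  with_seed(seed, {
    for (b in seq_len(permutations)) {
      rs <- shuffle_correlations(net$r, host_labels, per_sample = per_sample)
      nets <- build_graph(rs, negative_policy = policy)
      q_null[b] <- leading_eigenvector_communities(nets)$modularity
    }
  })
  list(q_obs = obs$modularity, q_null = q_null,
       p_value = mean(q_null >= obs$modularity),
       n_modules_obs = obs$n_modules)
}

#' Chi-squared association between modules and a design factor
#'
#' Pearson chi-squared test on the factor x module contingency table,
#' without continuity correction; df = (levels - 1)(modules - 1).
#'
#' @param partition `coral_modules` or membership vector.
#' @param labels factor of design-factor levels, one per sample.
#' @return data.frame with columns `df`, `statistic`, `p`.
#' @export
module_factor_chisq <- function(partition, labels) {
  membership <- if (inherits(partition, "coral_modules")) partition$membership
                else partition
  tab <- table(as.factor(labels), as.factor(membership))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("contingency table has an empty row or column")
  fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
  data.frame(df = unname(fit$parameter), statistic = unname(fit$statistic),
             p = fit$p.value)
}

#' Classification rate of a factor by module majority vote
#'
#' Labels each module with its majority factor level (ties broken toward the
#' level appearing first in factor-level order) and returns the fraction of
#' samples the vote classifies correctly.
#'
#' @param partition `coral_modules` or membership vector.
#' @param labels factor of design-factor levels, one per sample.
#' @return fraction of correctly classified samples in \[0, 1\].
#' @export
misclassification_rate <- function(partition, labels) {
  membership <- if (inherits(partition, "coral_modules")) partition$membership
                else partition
  labels <- as.factor(labels)
  tab <- table(membership, labels)   # label columns in factor-level order;
  correct <- sum(apply(tab, 1, max)) # max.col/"first" ties go to first level
  correct / length(labels)
}

#' Eigenvector centrality with per-factor group comparisons
#'
#' Leading eigenvector of the non-negative weight matrix, computed by power
#' iteration on the largest connected component (nodes outside it score 0),
#' scaled so the maximum centrality is 1.  When metadata is supplied, group
#' means and standard errors per factor are reported along with pairwise
#' Welch t-tests, Holm-adjusted within each factor.
#'
#' @param x `coral_network` with weights, igraph graph, or weight matrix.
#' @param metadata optional `coral_metadata` or data.frame of factors.
#' @param factors factor columns to summarize (default genus, species,
#'   site, time intersected with what metadata has).
#' @param tol power-iteration convergence tolerance (default 1e-10).
#' @param max_iter iteration cap; exceeding it errors with the estimated
#'   spectral gap.
#' @return object of class `coral_centrality`: list with `scores` (named
#'   vector, max 1), `groups` (per-factor data.frame level/mean/se/n), and
#'   `comparisons` (per-factor data.frame of pairwise Welch tests with
#'   `p_adj`).
#' @export
eigen_centrality_scores <- function(x, metadata = NULL,
                                    factors = c("genus", "species", "site", "time"),
                                    tol = 1e-10, max_iter = 100000) {
  w <- weight_matrix(x)
  n <- nrow(w)
  if (n == 0) stop("empty graph")
  ids <- rownames(w) %||% as.character(seq_len(n))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  main <- which(comp$membership == which.max(comp$csize))
  scores <- setNames(numeric(n), ids)
  wm <- w[main, main, drop = FALSE]
  ## diagonal shift keeps the Perron eigenvalue strictly dominant in
  ## magnitude (bipartite components otherwise make the iteration oscillate
  ## between +lambda and -lambda); eigenvectors are unchanged
  shift <- max(rowSums(wm))
  if (shift == 0) stop("zero-weight component; centrality undefined")
  v <- rep(1 / sqrt(length(main)), length(main))
  lambda <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    v_new <- as.vector(wm %*% v) + shift * v
    nrm <- sqrt(sum(v_new^2))
    v_new <- v_new / nrm
    lambda <- nrm - shift
    if (max(abs(v_new - v)) < tol) { v <- v_new; converged <- TRUE; break }
    v <- v_new
  }
  if (!converged) {
    resid <- max(abs(as.vector(wm %*% v) - lambda * v)) / max(lambda, 1e-12)
    stop("power iteration did not converge after ", max_iter,
         " iterations (relative residual ", signif(resid, 3),
         "); spectral gap may be (near-)degenerate")
  }
  v <- abs(v)                 # Perron vector is non-negative
  scores[main] <- v / max(v)  # max-normalized

  groups <- comparisons <- NULL
  if (!is.null(metadata)) {
    samples <- if (inherits(metadata, "coral_metadata")) metadata$samples else metadata
    samples <- samples[ids, , drop = FALSE]
    factors <- intersect(factors, names(samples))
    groups <- lapply(factors, function(f) {
      lv <- levels(as.factor(samples[[f]]))
      do.call(rbind, lapply(lv, function(l) {
        sc <- scores[samples[[f]] == l]
        data.frame(level = l, mean = mean(sc),
                   se = sd(sc) / sqrt(length(sc)), n = length(sc),
                   stringsAsFactors = FALSE)
      }))
    })
    names(groups) <- factors
    comparisons <- lapply(factors, function(f) {
      fl <- as.factor(samples[[f]])
      prs <- utils::combn(levels(fl), 2)
      out <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
        a <- scores[fl == prs[1, k]]; b <- scores[fl == prs[2, k]]
        tt <- tryCatch(t.test(a, b), error = function(e) NULL)
        data.frame(level1 = prs[1, k], level2 = prs[2, k],
                   diff = mean(a) - mean(b),
                   p = if (is.null(tt)) NA_real_ else tt$p.value,
                   stringsAsFactors = FALSE)
      }))
      ok <- !is.na(out$p)
      out$p_adj <- NA_real_
      out$p_adj[ok] <- holm_adjust(out$p[ok])
      out
    })
    names(comparisons) <- factors
  }
  structure(list(scores = scores, lambda = lambda,
                 groups = groups, comparisons = comparisons),
            class = "coral_centrality")
}

#' @export
print.coral_centrality <- function(x, ...) {
  cat("coral_centrality:", length(x$scores), "nodes; leading eigenvalue",
      signif(x$lambda, 5), "\n")
  if (!is.null(x$groups$genus)) {
    cat("mean centrality by genus:\n"); print(x$groups$genus)
  }
  invisible(x)
}
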