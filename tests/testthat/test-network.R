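test_that("sample correlations match hand-computed Pearson values", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1), d = c(1, 2, 4))
  colnames(m) <- paste0("o", 1:3)
  net <- sample_correlation(m)
  expect_equal(net$r["a", "b"], 1)
  expect_equal(net$r["a", "c"], -1)
  expect_equal(net$r["a", "d"], cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(net$r["a", "d"], 0.98198051, tolerance = 1e-7)
  const <- rbind(a = c(2, 2, 2), b = c(1, 2, 3))
  colnames(const) <- paste0("o", 1:3)
  expect_error(sample_correlation(const), "constant.*a")
})

test_that("homophily and heterophily average the right correlation pairs", {
  ## constant construction: within 0.5, between 0.1
  lab <- rep(c("A", "B"), each = 3)
  r <- outer(lab, lab, function(x, y) ifelse(x == y, 0.5, 0.1))
  diag(r) <- 1
  h <- homophily(r, lab)
  expect_equal(h$homophily, 0.5)
  expect_equal(h$heterophily, 0.1)
  expect_equal(h$n_within, 6)          # 2 * C(3,2)
  expect_equal(h$n_between, 9)
  ## single level: heterophily undefined
  expect_warning(h1 <- homophily(r, rep("A", 6)), "single level")
  expect_true(is.nan(h1$heterophily))
  ## singleton level warns
  expect_warning(homophily(r, c("A", rep("B", 5))), "single sample")
  ## invariant to sample relabeling/reordering
  ord <- c(4, 1, 6, 2, 5, 3)
  h2 <- homophily(r[ord, ord], lab[ord])
  expect_equal(h2$homophily, h$homophily)
  expect_equal(h2$heterophily, h$heterophily)
})

test_that("negative-weight policies map correlations as declared", {
  r <- matrix(c(1, 0.8, -0.3, 0.8, 1, 0, -0.3, 0, 1), 3, 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  tr <- build_graph(r, "truncate")
  expect_equal(tr$w["s1", "s2"], 0.8)
  expect_equal(tr$w["s1", "s3"], 0)                  # edge removed
  sh <- build_graph(r, "shift")
  expect_equal(sh$w["s1", "s3"], 0.35)               # (r+1)/2
  ab <- build_graph(r, "absolute")
  expect_equal(ab$w["s1", "s3"], 0.3)
  rp <- abs(r)
  expect_equal(build_graph(rp, "truncate")$w, build_graph(rp, "absolute")$w)
  expect_equal(igraph::ecount(tr$graph), 1)
})

test_that("modularity matches hand values on canonical graphs", {
  w <- two_triangles()
  expect_equal(modularity_q(w, rep(1, 6)), 0)                  # all-in-one
  expect_equal(modularity_q(w, rep(c(1, 2), each = 3)), 0.5)   # true split
  ## singleton modules on a clique are worse than chance
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  dimnames(k4) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_lt(modularity_q(k4, 1:4), 0)
  expect_error(modularity_q(w, c(1, 2, NA, 1, 2, 1)), "missing")
})

test_that("leading-eigenvector detection recovers planted structure", {
  ## two disconnected triangles -> 2 modules, Q = 0.5
  mod <- leading_eigenvector_communities(two_triangles())
  expect_equal(mod$n_modules, 2)
  expect_equal(mod$modularity, 0.5)
  ## complete graph: no positive split
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  dimnames(k6) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_equal(leading_eigenvector_communities(k6)$n_modules, 1)
  ## planted weighted 2-block graph: blocks recovered, Q equals the
  ## exhaustive bipartition-refinement maximum
  pb <- planted_block_graph(c(5, 5), cross = 0.05)
  mod2 <- leading_eigenvector_communities(pb$w)
  expect_equal(mod2$n_modules, 2)
  expect_equal(unname(split(names(mod2$membership), mod2$membership)$`1`),
               paste0("s", 1:5))
  expect_equal(mod2$modularity, brute_modularity_max(pb$w), tolerance = 1e-9)
})

test_that("detected modularity matches the exhaustive oracle on small block graphs", {
  set.seed(12)
  for (i in 1:6) {
    sizes <- sample(2:4, sample(2:3, 1), replace = TRUE)
    pb <- planted_block_graph(sizes, cross = runif(1, 0.02, 0.15))
    ## jitter weights so no two eigenvalues tie
    noise <- matrix(runif(sum(sizes)^2, 0, 0.02), sum(sizes))
    w <- pb$w + (noise + t(noise)) / 2; diag(w) <- 0
    mod <- leading_eigenvector_communities(w)
    expect_equal(mod$modularity, brute_modularity_max(w), tolerance = 1e-9)
    expect_gte(mod$modularity, 0)    # never worse than the trivial partition
  }
})

test_that("detection agrees with igraph's leading-eigenvector on planted blocks", {
  pb <- planted_block_graph(c(6, 4), cross = 0.05)
  g <- igraph::graph_from_adjacency_matrix(pb$w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ref <- igraph::cluster_leading_eigen(g)
  ours <- leading_eigenvector_communities(pb$w)
  expect_equal(ours$modularity,
               igraph::modularity(g, igraph::membership(ref),
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-9)
})

test_that("stratified shuffling preserves each stratum's correlation multiset", {
  set.seed(19)
  n <- 10
  r <- matrix(runif(n * n, -1, 1), n); r <- (r + t(r)) / 2; diag(r) <- 1
  dimnames(r) <- list(paste0("s", 1:n), paste0("s", 1:n))
  strata <- rep(c("A", "B"), each = 5)
  shuf <- coralnet:::shuffle_correlations(r, strata, symmetrize = FALSE)
  ## compare multisets of off-diagonal values per stratum
  offdiag_vals <- function(m, rows) {
    v <- c()
    for (u in rows) v <- c(v, m[u, -u])
    sort(unname(v))
  }
  for (s in c("A", "B")) {
    rows <- which(strata == s)
    expect_equal(offdiag_vals(shuf, rows), offdiag_vals(r, rows))
  }
})

test_that("modularity null detects planted structure and is seed-stable", {
  pb <- planted_block_graph(c(6, 6), cross = 0.05)
  ## dress the blocks up as a correlation matrix
  r <- pb$w; diag(r) <- 1
  net <- build_graph(r, "truncate")
  labels <- rep(c("A", "B"), each = 6)
  null <- modularity_null(net, labels, permutations = 99, seed = 4)
  expect_equal(null$p_value, 0)        # no shuffled network beats the blocks
  expect_equal(length(null$q_null), 99)
  null2 <- modularity_null(net, labels, permutations = 99, seed = 4)
  expect_identical(null$q_null, null2$q_null)
})

test_that("module-factor chi-squared matches hand and closed-form df", {
  out <- module_factor_chisq(rep(c(1, 2), each = 10),
                             rep(c("A", "B"), each = 10))
  expect_equal(out$statistic, 20)
  expect_equal(out$df, 1)
  expect_equal(out$p, pchisq(20, 1, lower.tail = FALSE))
  ## 6 species x 6 modules -> df 25
  set.seed(13)
  sp <- factor(rep(paste0("sp", 1:6), each = 6))
  mods <- rep(1:6, 6)
  expect_equal(module_factor_chisq(mods, sp)$df, 25)
  expect_error(module_factor_chisq(rep(1, 4), factor(c("A", "A", "B", "B"),
                                                     levels = c("A", "B", "C"))),
               "empty")
})

test_that("classification rate is the module-majority correct fraction", {
  part <- c(rep(1, 20), rep(2, 10))
  lab <- c(rep("A", 19), "B", rep("B", 10))
  expect_equal(misclassification_rate(part, lab), 29 / 30)
  expect_equal(misclassification_rate(rep(c(1, 2), each = 5),
                                      rep(c("A", "B"), each = 5)), 1)
})

test_that("eigenvector centrality matches closed forms and the eigen equation", {
  ## complete graph: symmetry forces all centralities to 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  dimnames(k5) <- list(paste0("s", 1:5), paste0("s", 1:5))
  cen <- eigen_centrality_scores(k5)
  expect_equal(unname(cen$scores), rep(1, 5))
  ## star K_{1,3}: center 1, leaves 1/sqrt(3)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star[2:4, 1] <- 1
  dimnames(star) <- list(paste0("s", 1:4), paste0("s", 1:4))
  cs <- eigen_centrality_scores(star)
  expect_equal(unname(cs$scores), c(1, rep(1 / sqrt(3), 3)), tolerance = 1e-8)
  ## eigen residual on a weighted random graph + igraph cross-check
  set.seed(14)
  w <- matrix(runif(64), 8); w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(paste0("s", 1:8), paste0("s", 1:8))
  ce <- eigen_centrality_scores(w)
  x <- ce$scores
  expect_lt(max(abs(w %*% x - ce$lambda * x)) / ce$lambda, 1e-8)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ref <- igraph::eigen_centrality(g, weights = igraph::E(g)$weight)$vector
  expect_equal(unname(x), unname(ref), tolerance = 1e-6)
  ## nodes outside the largest component score zero
  wdis <- matrix(0, 5, 5)
  wdis[1:3, 1:3] <- 1; wdis[4, 5] <- wdis[5, 4] <- 0.5; diag(wdis) <- 0
  dimnames(wdis) <- list(paste0("s", 1:5), paste0("s", 1:5))
  cd <- eigen_centrality_scores(wdis)
  expect_equal(unname(cd$scores[4:5]), c(0, 0))
  expect_equal(max(cd$scores), 1)
})

test_that("centrality group summaries include Holm-adjusted Welch tests", {
  sim <- fixture_small(2)
  norm <- normalize_median_of_ratios(sim$counts, "pseudo-geomean")
  net <- build_graph(sample_correlation(norm))
  cen <- eigen_centrality_scores(net, sim$metadata)
  expect_named(cen$groups, c("genus", "species", "site", "time"))
  expect_equal(sum(cen$groups$genus$n), 12)
  cmp <- cen$comparisons$site
  expect_equal(nrow(cmp), 3)        # three site pairs
  ok <- !is.na(cmp$p)
  expect_equal(cmp$p_adj[ok], holm_adjust(cmp$p[ok]))
})
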