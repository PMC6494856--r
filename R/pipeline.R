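## End-to-end orchestration: normalize -> core -> class profiles ->
## Bray-Curtis -> PERMANOVA (+ pairwise) -> SIMPER -> distance-decay ANCOVA
## -> network suite, with per-stage seeds and a JSON run manifest.

#' Default PERMANOVA term list for the nested crossed survey design
#'
#' Genus, Site, Time, Species nested in Genus, and all their two- and
#' three-way interactions, in the order they are tested sequentially.
#'
#' @return character vector of terms.
#' @export
default_terms <- function() {
  c("genus", "site", "time", "species(genus)",
    "genus:site", "genus:time", "site:time",
    "species(genus):site", "species(genus):time",
    "genus:site:time", "species(genus):site:time")
}

## Keep only terms that add rank to the cumulative design (drop aliased
## terms, e.g. species nested in genus when there is one species per genus)
## and that leave at least one residual degree of freedom.  Used when
## run_all() derives the term list automatically.
prune_terms <- function(samples, terms) {
  n <- nrow(samples)
  varying <- names(samples)[vapply(samples, function(x)
    length(unique(x)) > 1, logical(1))]
  terms <- terms[vapply(terms, function(tm)
    all(parse_term(tm) %in% varying), logical(1))]
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  keep <- character(0)
  for (tm in terms) {
    Xc <- cbind(X, term_indicators(samples, tm))
    rk <- qr(Xc)$rank
    if (rk > rank_prev && n - rk >= 1) {
      keep <- c(keep, tm)
      X <- Xc; rank_prev <- rk
    }
  }
  keep
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a count table + metadata (+ taxonomy): size-factor
#' normalization, core-microbiome detection, class abundance profiles,
#' Bray-Curtis dissimilarity, sequential PERMANOVA with pairwise post-hoc
#' tests for genus/site/time, SIMPER for all genus pairs, the distance-decay
#' Monte-Carlo ANCOVA, and the correlation-network suite (homophily,
#' modules, modularity null, chi-squared associations, classification rates,
#' eigencentrality).  One seed fans out to fixed per-stage substreams, so
#' results are reproducible and stable under stage skipping.
#'
#' @param counts samples x OTUs count matrix.
#' @param metadata `coral_metadata`.
#' @param taxonomy optional `coral_taxonomy`.
#' @param zero_policy normalization policy (see
#'   [normalize_median_of_ratios()]); default `"pseudo-geomean"`, which is
#'   defined for sparse tables.
#' @param core_threshold core prevalence threshold (default 0.95).
#' @param terms PERMANOVA terms (default [default_terms()], pruned to the
#'   factors actually varying in the data).
#' @param permutations permutations for PERMANOVA/ANCOVA/network null
#'   (default 999).
#' @param seed master integer seed (default 17).
#' @param negative_policy network negative-weight policy (default
#'   `"truncate"`).
#' @param out_dir optional directory; when given, every result table is
#'   written as CSV/JSON plus a `manifest.json` recording seeds, config and
#'   per-stage wall time.
#' @param skip character vector of stages to skip, among `"core"`,
#'   `"permanova"`, `"pairwise"`, `"simper"`, `"distance_decay"`,
#'   `"network"`.
#' @return named list of stage results (class `coral_run`).
#' @export
run_all <- function(counts, metadata, taxonomy = NULL,
                    zero_policy = "pseudo-geomean",
                    core_threshold = 0.95,
                    terms = NULL,
                    permutations = 999,
                    seed = 17,
                    negative_policy = "truncate",
                    out_dir = NULL,
                    skip = character()) {
  validate_counts(counts)
  samples <- metadata$samples[rownames(counts), , drop = FALSE]
  stage_seed <- function(k) (seed * 97 + k * 1009) %% .Machine$integer.max
  res <- list()
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  res$normalized <- tick("normalize",
    normalize_median_of_ratios(counts, zero_policy = zero_policy))

  if (!"core" %in% skip) {
    res$core <- tick("core",
      core_microbiome(counts, samples$genus, threshold = core_threshold,
                      normalized = res$normalized, taxonomy = taxonomy))
    if (!is.null(taxonomy))
      res$class_profile <- tick("class_profile",
        class_abundance_profile(res$normalized, taxonomy, samples$genus))
  }

  res$bray_curtis <- tick("bray_curtis", bray_curtis(res$normalized))

  if (!"permanova" %in% skip) {
    if (is.null(terms)) terms <- prune_terms(samples, default_terms())
    res$permanova <- tick("permanova",
      permanova(res$bray_curtis, metadata, terms,
                permutations = permutations, seed = stage_seed(1)))
  }
  if (!"pairwise" %in% skip) {
    res$pairwise <- tick("pairwise", {
      out <- list()
      for (f in c("genus", "site", "time"))
        if (nlevels(samples[[f]]) > 1)
          out[[f]] <- pairwise_permanova(res$bray_curtis, samples[[f]],
                                         permutations = permutations,
                                         seed = stage_seed(2))
      out
    })
  }
  if (!"simper" %in% skip && nlevels(samples$genus) > 1) {
    res$simper <- tick("simper", {
      prs <- utils::combn(levels(samples$genus), 2)
      out <- lapply(seq_len(ncol(prs)), function(k)
        simper(res$normalized, samples$genus, prs[, k], taxonomy = taxonomy))
      names(out) <- apply(prs, 2, paste, collapse = "_vs_")
      out
    })
  }
  if (!"distance_decay" %in% skip && !is.null(metadata$sites) &&
      nlevels(samples$site) > 1) {
    res$distance_decay <- tick("distance_decay",
      distance_decay_table(res$bray_curtis, metadata))
    n_par <- 2 * length(unique(res$distance_decay$genus))  # 1 + 1 + (G-1) + (G-1)
    if (nrow(res$distance_decay) > n_par)
      res$ancova <- tick("ancova",
        ancova_mc(res$distance_decay, permutations = permutations,
                  seed = stage_seed(3)))
    else
      message("distance-decay table too small for the ANCOVA model; skipped")
  }
  if (!"network" %in% skip) {
    res$network <- tick("network", {
      net <- build_graph(sample_correlation(res$normalized),
                         negative_policy = negative_policy)
      modules <- leading_eigenvector_communities(net)
      factors <- c("genus", "site", "time")
      list(
        net = net,
        homophily = homophily_scores(net, metadata, factors = factors),
        modules = modules,
        null = modularity_null(net, samples$genus,
                               permutations = permutations,
                               seed = stage_seed(4)),
        chisq = do.call(rbind, lapply(c("species", factors), function(f)
          cbind(factor = f, module_factor_chisq(modules, samples[[f]])))),
        classification = vapply(factors, function(f)
          misclassification_rate(modules, samples[[f]]), numeric(1)),
        centrality = eigen_centrality_scores(net, metadata)
      )
    })
  }

  if (!is.null(out_dir)) write_run(res, out_dir, seed = seed,
                                   permutations = permutations,
                                   zero_policy = zero_policy,
                                   core_threshold = core_threshold,
                                   negative_policy = negative_policy,
                                   timings = timings)
  structure(res, class = "coral_run", timings = timings, seed = seed)
}

## Serialize every stage result plus a manifest.
write_run <- function(res, out_dir, timings, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  if (!is.null(res$normalized))
    write_results(data.frame(sample = names(res$normalized$size_factors),
                             size_factor = res$normalized$size_factors),
                  pth("size_factors.csv"))
  if (!is.null(res$core)) {
    core_json <- lapply(res$core, function(g)
      list(core = g$core,
           prevalence = as.list(g$prevalence[g$core]),
           class_profile = as.list(g$class_profile)))
    write_results(core_json, pth("core_microbiome.json"), format = "json")
  }
  if (!is.null(res$class_profile))
    write_results(data.frame(group = rownames(res$class_profile),
                             res$class_profile, check.names = FALSE),
                  pth("class_profiles.csv"))
  if (!is.null(res$permanova))
    write_results(as.data.frame(res$permanova), pth("permanova.csv"))
  if (!is.null(res$pairwise))
    for (f in names(res$pairwise))
      write_results(res$pairwise[[f]], pth(paste0("pairwise_", f, ".csv")))
  if (!is.null(res$simper))
    for (nm in names(res$simper))
      write_results(res$simper[[nm]]$otu, pth(paste0("simper_", nm, ".csv")))
  if (!is.null(res$distance_decay))
    write_results(res$distance_decay, pth("distance_decay.csv"))
  if (!is.null(res$ancova))
    write_results(as.data.frame(res$ancova), pth("ancova.csv"))
  if (!is.null(res$network)) {
    nw <- res$network
    write_results(nw$homophily, pth("homophily.csv"))
    write_results(data.frame(sample = names(nw$modules$membership),
                             module = nw$modules$membership,
                             centrality = nw$centrality$scores),
                  pth("network_nodes.csv"))
    write_results(nw$chisq, pth("module_chisq.csv"))
    w <- nw$net$w
    ij <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    write_results(data.frame(sample_a = rownames(w)[ij[, 1]],
                             sample_b = colnames(w)[ij[, 2]],
                             weight = w[ij]),
                  pth("network_edges.csv"))
    write_results(list(modularity = nw$modules$modularity,
                       n_modules = nw$modules$n_modules,
                       p_value = nw$null$p_value,
                       classification = as.list(nw$classification)),
                  pth("network_summary.json"), format = "json")
  }
  manifest <- c(list(package = "coralnet",
                     version = as.character(utils::packageVersion("coralnet")),
                     r_version = R.version.string,
                     timings_sec = as.list(timings)),
                list(...))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.coral_run <- function(x, ...) {
  cat("coral_run with stages:", paste(names(x), collapse = ", "), "\n")
  if (!is.null(x$permanova)) { cat("\nPERMANOVA:\n"); print(as.data.frame(x$permanova)) }
  if (!is.null(x$network)) {
    cat("\nNetwork:", x$network$modules$n_modules, "modules, Q =",
        signif(x$network$modules$modularity, 4),
        ", null p =", x$network$null$p_value, "\n")
  }
  invisible(x)
}
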