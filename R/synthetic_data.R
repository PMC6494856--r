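## Synthetic coral-microbiome survey generator.  Emulates the study design
## the analysis pipeline assumes: colonies from several coral genera (two
## species each) sampled repeatedly at a handful of reef sites over a year,
## with genus-specific core OTUs, host/site/time log-abundance effects of
## controllable magnitude, spatially decaying site similarity, log-normal
## library sizes, and negative-binomial counts.

#' Default site coordinates for simulations
#'
#' Four reef sites in the Bocas del Toro archipelago (Panama) — two
#' protected inshore reefs (PC, CB) and two exposed offshore reefs (CK14,
#' CK4) — spanning roughly 3 to 24 km of separation, a realistic scale for
#' fine-grained distance-decay structure.
#'
#' @return data.frame with columns `site`, `lat`, `lon`.
#' @export
default_sites <- function() {
  data.frame(site = c("PC", "CB", "CK14", "CK4"),
             lat = c(9.37804, 9.36028, 9.25398, 9.25862),
             lon = c(-82.30335, -82.27760, -82.12595, -82.12708),
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Builds the parameter list for [simulate_survey()].  Defaults describe the
#' emulated survey: 3 genera x 2 species x 4 sites x 4 colonies = 96 tagged
#' colonies, each sampled at 3 time points (288 samples); genus effects
#' stronger than site effects, which are stronger than time effects, on the
#' log-abundance scale; site effects spatially correlated with an
#' exponential kernel over great-circle distance.
#'
#' @param n_genera number of host genera (default 3).
#' @param species_per_genus species nested in each genus (default 2).
#' @param n_sites number of sites (default 4, must match `sites` rows).
#' @param n_times number of time points (default 3).
#' @param colonies_per_cell colonies per species x site cell (default 4).
#' @param n_otus number of OTUs (default 200).
#' @param sigma_genus,sigma_site,sigma_time standard deviations of the
#'   genus/site/time log-abundance effects (defaults 1.2, 0.6, 0.3).
#' @param sigma_noise per-sample log-abundance noise sd (default 0.3).
#' @param spatial_range_km e-folding range of the exponential spatial
#'   kernel correlating site effects (default 10 km); 0 disables spatial
#'   correlation (independent site effects).
#' @param sites data.frame site/lat/lon (default [default_sites()]).
#' @param core_otus_per_genus planted core OTUs per genus (default 5).
#' @param core_occupancy occupancy floor for planted core OTUs within their
#'   genus (default 0.97; must exceed the 0.95 core-detection threshold).
#' @param core_boost log-abundance boost of a core OTU within its genus
#'   (default 3).
#' @param library_meanlog,library_sdlog log-normal library-size parameters
#'   (defaults log(2e4), 0.5).
#' @param nb_size negative-binomial size (inverse overdispersion, default 2).
#' @param base_sd sd of per-OTU baseline log-abundances (default 1.5).
#' @param seed integer seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genera = 3, species_per_genus = 2, n_sites = 4,
                       n_times = 3, colonies_per_cell = 4, n_otus = 200,
                       sigma_genus = 1.2, sigma_site = 0.6, sigma_time = 0.3,
                       sigma_noise = 0.3, spatial_range_km = 10,
                       sites = default_sites(),
                       core_otus_per_genus = 5, core_occupancy = 0.97,
                       core_boost = 3,
                       library_meanlog = log(2e4), library_sdlog = 0.5,
                       nb_size = 2, base_sd = 1.5, seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_sites > nrow(cfg$sites)) stop("not enough site coordinates")
  cfg$sites <- cfg$sites[seq_len(cfg$n_sites), , drop = FALSE]
  if (any(c(sigma_genus, sigma_site, sigma_time, sigma_noise) < 0))
    stop("effect scales must be >= 0")
  if (core_occupancy <= 0 || core_occupancy > 1)
    stop("infeasible occupancy target (must be in (0, 1])")
  structure(cfg, class = "sim_config")
}

## Genus / species naming: common Caribbean reef corals for the default
## three genera; generic names beyond that.
genus_names <- function(n) {
  base <- c("Porites", "Acropora", "Diploria")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("Genus", seq_len(n - 3)))
}
species_names <- function(genera, k) {
  sp <- list(Porites = c("astreoides", "furcata"),
             Acropora = c("cervicornis", "palmata"),
             Diploria = c("labyrinthiformis", "strigosa"))
  unlist(lapply(genera, function(g) {
    eps <- sp[[g]] %||% letters[seq_len(k)]
    paste(g, c(eps, paste0("sp", seq_len(max(0, k - length(eps)))))[seq_len(k)],
          sep = "_")
  }))
}

## Bacterial classes used for taxonomy; the first n_genera are the
## genus-signature classes planted into each genus's core.
class_pool <- function() {
  c("Gammaproteobacteria", "Epsilonproteobacteria", "Cytophagia",
    "Betaproteobacteria", "Alphaproteobacteria", "Flavobacteriia",
    "Bacilli", "Synechococcophycideae")
}
class_phylum <- function(cls) {
  switch(cls,
         Gammaproteobacteria = , Epsilonproteobacteria = ,
         Betaproteobacteria = , Alphaproteobacteria = "Proteobacteria",
         Cytophagia = , Flavobacteriia = "Bacteroidetes",
         Bacilli = "Firmicutes",
         Synechococcophycideae = "Cyanobacteria",
         "Unassigned")
}

#' Simulate a coral-microbiome survey
#'
#' Generates a count table, metadata, taxonomy, and the full ground truth
#' under the model
#' `lambda_ij = exp(base_i + genus_effect + site_effect + time_effect + eps)`,
#' where each sample's expected composition is `lambda / sum(lambda)`; counts
#' are negative binomial around `library_size * composition`.  Site effects
#' are drawn per OTU from a multivariate normal whose correlation decays
#' exponentially with great-circle distance between sites
#' (`exp(-d / spatial_range_km)`), so nearby sites receive similar
#' communities and dissimilarity increases with distance.  Planted core
#' OTUs get a large within-genus abundance boost plus a hard occupancy
#' floor, making the >95%-prevalence core recoverable by construction.
#'
#' @param config `sim_config` list.
#' @return object of class `coral_sim`: list with `counts` (samples x OTUs
#'   integer matrix), `metadata` (`coral_metadata`), `taxonomy`
#'   (`coral_taxonomy`), `truth` (baselines, effect matrices, planted core
#'   ids, class map), and `config`.
#' @export
simulate_survey <- function(config = sim_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    genera <- genus_names(cfg$n_genera)
    species <- species_names(genera, cfg$species_per_genus)
    sp_genus <- rep(genera, each = cfg$species_per_genus)
    sites <- cfg$sites$site
    times <- c("December", "April", "October")[seq_len(cfg$n_times)]
    if (cfg$n_times > 3) times <- c(times, paste0("T", seq_len(cfg$n_times - 3)))

    ## design: colonies_per_cell colonies per species x site, each colony
    ## sampled at every time point
    design <- expand.grid(colony = seq_len(cfg$colonies_per_cell),
                          site = sites, species = species,
                          stringsAsFactors = FALSE)
    design$genus <- sp_genus[match(design$species, species)]
    design$colony_id <- sprintf("%s_%s_c%d", design$species, design$site, design$colony)
    samples <- design[rep(seq_len(nrow(design)), each = cfg$n_times), ]
    samples$time <- rep(times, nrow(design))
    samples$sample <- paste(samples$colony_id, samples$time, sep = "_")
    n <- nrow(samples)
    p <- cfg$n_otus
    otus <- sprintf("OTU%04d", seq_len(p))

    ## taxonomy: first classes in the pool are genus signatures; core OTUs
    ## take their genus's signature class, the rest draw from the pool
    pool <- class_pool()
    sig_class <- setNames(pool[seq_along(genera)], genera)
    otu_class <- sample(pool, p, replace = TRUE,
                        prob = c(4, rep(2, min(2, length(pool) - 1)),
                                 rep(1, max(0, length(pool) - 3))))
    core_ids <- setNames(rep(list(character(0)), length(genera)), genera)
    nxt <- 1
    if (cfg$core_otus_per_genus > 0) {
      for (g in genera) {
        idx <- nxt:(nxt + cfg$core_otus_per_genus - 1)
        core_ids[[g]] <- otus[idx]
        otu_class[idx] <- sig_class[[g]]
        nxt <- nxt + cfg$core_otus_per_genus
      }
    }

    base <- rnorm(p, 0, cfg$base_sd)
    g_eff <- matrix(rnorm(length(genera) * p, 0, cfg$sigma_genus),
                    length(genera), p, dimnames = list(genera, otus))
    for (g in genera)                       # plant the core: big, genus-specific
      g_eff[g, match(core_ids[[g]], otus)] <- cfg$core_boost

    ## spatially correlated site effects: per OTU, MVN over sites with
    ## correlation exp(-d/rho)
    D <- outer(seq_len(cfg$n_sites), seq_len(cfg$n_sites),
               Vectorize(function(i, j)
                 haversine_km(cfg$sites$lat[i], cfg$sites$lon[i],
                              cfg$sites$lat[j], cfg$sites$lon[j])))
    R <- if (cfg$spatial_range_km > 0) exp(-D / cfg$spatial_range_km)
         else diag(cfg$n_sites)
    L <- chol(R)
    s_eff <- cfg$sigma_site *
      t(L) %*% matrix(rnorm(cfg$n_sites * p), cfg$n_sites, p)
    dimnames(s_eff) <- list(sites, otus)
    t_eff <- matrix(rnorm(cfg$n_times * p, 0, cfg$sigma_time),
                    cfg$n_times, p, dimnames = list(times, otus))

    loglam <- matrix(base, n, p, byrow = TRUE) +
      g_eff[samples$genus, , drop = FALSE] +
      s_eff[samples$site, , drop = FALSE] +
      t_eff[samples$time, , drop = FALSE] +
      matrix(rnorm(n * p, 0, cfg$sigma_noise), n, p)
    lam <- exp(loglam)
    comp <- lam / rowSums(lam)

    libsize <- rlnorm(n, cfg$library_meanlog, cfg$library_sdlog)
    counts <- matrix(rnbinom(n * p, mu = comp * libsize, size = cfg$nb_size),
                     n, p, dimnames = list(samples$sample, otus))

    ## occupancy floor for planted core OTUs within their genus
    for (g in genera) {
      rows <- which(samples$genus == g)
      for (otu in core_ids[[g]]) {
        col <- match(otu, otus)
        need <- ceiling(cfg$core_occupancy * length(rows))
        zero <- rows[counts[rows, col] == 0]
        have <- length(rows) - length(zero)
        if (have < need) {
          fix <- zero[sample.int(length(zero), need - have)]
          counts[fix, col] <- 1
        }
      }
    }
    ## no empty samples (vanishingly unlikely at default depth)
    empty <- rowSums(counts) == 0
    if (any(empty)) counts[empty, which.max(colMeans(counts))] <- 1

    metadata <- make_metadata(
      samples[, c("sample", "genus", "species", "site", "time")],
      sites = cfg$sites, counts = counts)
    lineage <- vapply(otu_class, function(cl)
      paste0("k__Bacteria; p__", class_phylum(cl), "; c__", cl,
             "; o__; f__; g__"), character(1))
    taxonomy <- make_taxonomy(otus, lineage)
    truth <- list(base = setNames(base, otus), genus_effects = g_eff,
                  site_effects = s_eff, time_effects = t_eff,
                  core_otus = core_ids,
                  class_map = setNames(otu_class, otus),
                  site_distances_km = D,
                  expected_composition = comp)
    structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy,
                   truth = truth, config = cfg),
              class = "coral_sim")
  })
}

#' @export
print.coral_sim <- function(x, ...) {
  cat("coral_sim:", nrow(x$counts), "samples x", ncol(x$counts), "OTUs\n")
  print(x$metadata)
  invisible(x)
}

#' Tiny deterministic fixture dataset
#'
#' A miniature survey (12 samples, 20 OTUs: two genera, three sites, two
#' time points, one colony per cell) with a very strong genus effect, so its
#' planted cores are recoverable at the 0.95 threshold and its two genus
#' blocks form two network modules.  Deterministic for a given seed.
#'
#' @param seed integer seed (default 1).
#' @return `coral_sim` object.
#' @export
fixture_small <- function(seed = 1) {
  simulate_survey(sim_config(
    n_genera = 2, species_per_genus = 1, n_sites = 3, n_times = 2,
    colonies_per_cell = 1, n_otus = 20,
    sigma_genus = 2.5, sigma_site = 0.3, sigma_time = 0.15,
    sigma_noise = 0.2, core_otus_per_genus = 3, core_occupancy = 1,
    library_meanlog = log(5e3), seed = seed))
}

#' Write a simulated dataset to disk
#'
#' Writes the count table (TSV), metadata (TSV, coordinates inline),
#' taxonomy (TSV), and ground truth (JSON) into a directory.
#'
#' @param sim `coral_sim` object.
#' @param dir output directory (created if needed).
#' @return named vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.json"))
  write_count_table(sim$counts, paths["counts"])
  md <- sim$metadata$samples
  md$lat <- sim$metadata$sites[as.character(md$site), "lat"]
  md$lon <- sim$metadata$sites[as.character(md$site), "lon"]
  write.table(md, paths["metadata"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$taxonomy[, c("otu", "lineage")], paths["taxonomy"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$expected_composition <- NULL   # bulky; regenerable from config + seed
  truth$genus_effects <- as.data.frame(truth$genus_effects)
  truth$site_effects <- as.data.frame(truth$site_effects)
  truth$time_effects <- as.data.frame(truth$time_effects)
  truth$site_distances_km <- as.data.frame(truth$site_distances_km)
  jsonlite::write_json(truth, paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
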