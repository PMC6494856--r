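test_that("Gower centering reproduces the classical sum-of-squares identity", {
  set.seed(2)
  y <- rnorm(8)
  G <- gower_center(as.matrix(dist(y)))
  expect_equal(sum(diag(G)), sum((y - mean(y))^2), tolerance = 1e-12)
  expect_equal(unname(rowSums(G)), rep(0, 8), tolerance = 1e-10)
  expect_equal(gower_center(matrix(0, 4, 4)), matrix(0, 4, 4))
  expect_error(gower_center(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA on Euclidean univariate data equals classical ANOVA", {
  ## the textbook 2x2 case: pseudo-F = 2
  y <- c(0, 1, 1, 2)
  d <- as.matrix(dist(y)); dimnames(d) <- list(letters[1:4], letters[1:4])
  md <- data.frame(g = c("A", "A", "B", "B"), row.names = letters[1:4])
  fit <- permanova(d, md, "g", permutations = 0)
  expect_equal(fit$F[1], 2.0, tolerance = 1e-12)

  ## multi-term sequential fit vs anova(lm) on unbalanced random designs
  set.seed(9)
  for (i in 1:5) {
    n <- 18
    y <- rnorm(n)
    A <- sample(c("a1", "a2", "a3"), n, replace = TRUE)
    B <- sample(c("b1", "b2"), n, replace = TRUE)
    md <- data.frame(A = A, B = B, row.names = paste0("s", 1:n))
    d <- as.matrix(dist(y)); dimnames(d) <- list(rownames(md), rownames(md))
    fit <- permanova(d, md, c("A", "B", "A:B"), permutations = 0)
    ref <- anova(lm(y ~ A * B, data = md))
    expect_equal(fit$SS[1:3], ref$`Sum Sq`[1:3], tolerance = 1e-9)
    expect_equal(fit$df[1:3], ref$Df[1:3])
    expect_equal(fit$F[1:3], ref$`F value`[1:3], tolerance = 1e-9)
    expect_equal(fit$SS[4], ref$`Sum Sq`[4], tolerance = 1e-9)
  }
})

test_that("PERMANOVA agrees with vegan::adonis2 on community data", {
  sim <- fixture_small(3)
  norm <- normalize_median_of_ratios(sim$counts, "pseudo-geomean")
  d <- bray_curtis(norm)
  md <- sim$metadata$samples
  fit <- permanova(d, sim$metadata, c("genus", "site", "time"), permutations = 0)
  ref <- vegan::adonis2(as.dist(d) ~ genus + site + time, data = md,
                        permutations = 2, by = "terms")
  expect_equal(fit$SS[1:3], ref$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(fit$F[1:3], ref$F[1:3], tolerance = 1e-9)
  expect_equal(fit$R2[1:3], ref$R2[1:3], tolerance = 1e-9)
})

test_that("nested survey design yields the expected degrees of freedom", {
  md <- survey_design()       # 3 genera / 6 species / 4 sites / 3 times
  set.seed(4)
  y <- matrix(rnorm(nrow(md) * 5), nrow(md))
  rownames(y) <- rownames(md)
  d <- as.matrix(dist(y)); dimnames(d) <- list(rownames(md), rownames(md))
  fit <- permanova(d, md,
                   c("genus", "site", "time", "species(genus)",
                     "genus:site", "species(genus):site"),
                   permutations = 0)
  expect_equal(fit$df[fit$term == "genus"], 2L)
  expect_equal(fit$df[fit$term == "site"], 3L)
  expect_equal(fit$df[fit$term == "time"], 2L)
  expect_equal(fit$df[fit$term == "species(genus)"], 3L)
  expect_equal(fit$df[fit$term == "genus:site"], 6L)
  ## R2 partition sums to 1
  expect_equal(sum(fit$R2[fit$term != "Total"]), 1, tolerance = 1e-9)
  ## aliased term is refused with its name
  expect_error(permanova(d, md, c("species", "genus"), permutations = 0),
               "'genus' is aliased")
})

test_that("permutation p-values are seed-reproducible and order-invariant in F", {
  sim <- fixture_small(5)
  norm <- normalize_median_of_ratios(sim$counts, "pseudo-geomean")
  d <- bray_curtis(norm)
  f1 <- permanova(d, sim$metadata, c("genus", "time"), permutations = 99, seed = 7)
  f2 <- permanova(d, sim$metadata, c("genus", "time"), permutations = 99, seed = 7)
  expect_identical(f1$p, f2$p)
  ## reordering samples leaves the observed statistics unchanged
  ord <- rev(seq_len(nrow(d)))
  f3 <- permanova(d[ord, ord], sim$metadata, c("genus", "time"), permutations = 0)
  expect_equal(f3$F[1:2], f1$F[1:2], tolerance = 1e-12)
  expect_equal(f3$R2[1:2], f1$R2[1:2], tolerance = 1e-12)
})

test_that("pairwise PERMANOVA covers all level pairs with Holm adjustment", {
  sim <- simulate_survey(sim_config(
    n_genera = 3, species_per_genus = 1, n_sites = 2, n_times = 1,
    colonies_per_cell = 3, n_otus = 40, sigma_genus = 2, sigma_site = 0.2,
    core_otus_per_genus = 2, seed = 6))
  d <- bray_curtis(normalize_median_of_ratios(sim$counts, "pseudo-geomean"))
  pw <- pairwise_permanova(d, sim$metadata$samples$genus,
                           permutations = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, holm_adjust(pw$p))
  expect_true(all(pw$p_adj >= pw$p))
  expect_error(pairwise_permanova(d, factor(rep("x", nrow(d)))), ">= 2 levels")
})

test_that("Holm adjustment reproduces hand-computed step-down values", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(c(0.04, 0.04)), c(0.08, 0.08))
  expect_true(all(diff(holm_adjust(c(0.001, 0.01, 0.04))[c(1, 2, 3)]) >= 0))
  expect_error(holm_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(holm_adjust(1.2), "\\(0, 1\\]")
})

test_that("haversine distance matches a spherical-law-of-cosines oracle", {
  expect_equal(haversine_km(9.4, -82.3, 9.4, -82.3), 0)
  slc <- function(lat1, lon1, lat2, lon2) {
    r <- pi / 180
    6371.0 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                         cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)))
  }
  s <- default_sites()
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(haversine_km(s$lat[i], s$lon[i], s$lat[j], s$lon[j]),
                 slc(s$lat[i], s$lon[i], s$lat[j], s$lon[j]),
                 tolerance = 1e-6)
  }
  expect_equal(haversine_km(s$lat[1], s$lon[1], s$lat[2], s$lon[2]),
               3.4, tolerance = 0.05)
})

test_that("distance-decay table has one row per genus and site pair", {
  sim <- simulate_survey(sim_config(colonies_per_cell = 1, n_otus = 40, seed = 2))
  d <- bray_curtis(normalize_median_of_ratios(sim$counts, "pseudo-geomean"))
  ddt <- distance_decay_table(d, sim$metadata)
  expect_equal(nrow(ddt), 3 * choose(4, 2))     # 18 rows
  expect_true(all(ddt$distance_km > 0))
  ## doubling dissimilarities doubles means, leaves distances unchanged
  ddt2 <- distance_decay_table(2 * d, sim$metadata)
  expect_equal(ddt2$mean_bc, 2 * ddt$mean_bc)
  expect_equal(ddt2$se_bc, 2 * ddt$se_bc)
  expect_equal(ddt2$distance_km, ddt$distance_km)
  ## constant dissimilarities give SE = 0
  dc <- d; dc[] <- 0.4; diag(dc) <- 0
  ddtc <- distance_decay_table(dc, sim$metadata)
  expect_equal(ddtc$mean_bc, rep(0.4, 18))
  expect_equal(ddtc$se_bc, rep(0, 18))
})

test_that("Monte-Carlo ANCOVA recovers an exact power law with the sequential term layout", {
  s <- default_sites()
  pairs <- t(combn(1:4, 2))
  dist_km <- haversine_km(s$lat[pairs[, 1]], s$lon[pairs[, 1]],
                          s$lat[pairs[, 2]], s$lon[pairs[, 2]])
  b <- 0.35
  ddt <- do.call(rbind, lapply(c("P", "A", "D"), function(g) {
    cc <- c(P = 0.30, A = 0.35, D = 0.40)[[g]]
    data.frame(genus = g, site1 = s$site[pairs[, 1]], site2 = s$site[pairs[, 2]],
               distance_km = dist_km, mean_bc = cc * dist_km^b,
               se_bc = 0, n_pairs = 10)
  }))
  fit <- ancova_mc(ddt, permutations = 199, seed = 3)
  expect_equal(fit$df[1:3], c(1L, 2L, 2L))      # Distance, Genus, interaction
  expect_equal(attr(fit, "slope"), b, tolerance = 1e-10)
  ## parallel power laws: interaction carries (numerically) zero SS
  expect_lt(fit$eta2[3], 1e-20)
  ## distance effect is exact: no shuffled F can realistically exceed it
  expect_equal(fit$p[1], 0)
  ## sequential OLS core agrees with anova(lm) on noisy data
  set.seed(10)
  ddt$mean_bc <- ddt$mean_bc * exp(rnorm(18, 0, 0.2))
  fit2 <- ancova_mc(ddt, permutations = 0)
  ref <- anova(lm(log(mean_bc) ~ log(distance_km) * genus, data = ddt))
  expect_equal(fit2$F[1:3], ref$`F value`[1:3], tolerance = 1e-9)
  expect_equal(fit2$df[1:3], ref$Df[1:3])
  expect_equal(fit2$eta2[1:3],
               (ref$`Sum Sq` / sum(ref$`Sum Sq`))[1:3], tolerance = 1e-9)
})
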