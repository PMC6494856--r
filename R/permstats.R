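## Sequential (Type-I) PERMANOVA on distance matrices, pairwise post-hoc
## comparisons with sequential Bonferroni (Holm) correction, and the
## distance-decay permutation ANCOVA.

#' Gower-center a distance matrix
#'
#' McArdle-Anderson machinery for partitioning a distance matrix:
#' `A = -d^2/2`, `G = (I - 11'/n) A (I - 11'/n)`.  `trace(G)` is the total
#' sum of squares; for Euclidean distances of univariate data it equals
#' `sum((y - mean(y))^2)`.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return centered inner-product matrix G (row and column sums zero).
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  a <- -0.5 * d^2
  rm_ <- rowMeans(a); cm_ <- colMeans(a); mm <- mean(a)
  sweep(sweep(a, 1, rm_), 2, cm_) + mm
}

## Parse a term string like "Genus", "Species(Genus)" or "Genus:Site" into
## the variable names whose interaction spans the term's column space.
## Nesting "A(B)" contributes both A and B; the realized rank (after the
## preceding terms) yields the nested degrees of freedom.
parse_term <- function(term) {
  term <- gsub(" ", "", term)
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([^()]+)\\(([^()]+)\\)$", p))[[1]]
    if (length(m)) c(m[2], m[3]) else p
  }))
}

## Indicator matrix for the interaction of the named factors.
term_indicators <- function(samples, term) {
  vars <- parse_term(term)
  miss <- setdiff(vars, names(samples))
  if (length(miss)) stop("unknown factor in term '", term, "': ",
                         paste(miss, collapse = ", "))
  f <- if (length(vars) == 1) factor(samples[[vars]])
       else droplevels(interaction(samples[vars], drop = TRUE))
  stats::model.matrix(~ 0 + f)
}

#' Sequential PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squares of a distance matrix by a sequence of
#' model terms (Type-I: each term is adjusted for all terms before it, in
#' the order given).  Terms may be factors (`"Genus"`), nested factors
#' (`"Species(Genus)"`), or interactions (`"Genus:Site"`,
#' `"Species(Genus):Time"`).  Degrees of freedom are realized projector-rank
#' differences, so rank-deficient interactions (empty design cells) report
#' the rank actually added.  Significance is assessed by free permutation of
#' the sample labels of the distance matrix (optionally within strata):
#' `p = (1 + #\{F* >= F\}) / (1 + permutations)`, ties counting as
#' exceedances.
#'
#' @param d distance matrix (`coral_dist`, `dist`, or plain symmetric matrix)
#'   with sample ids as dimnames.
#' @param metadata `coral_metadata`, or a data.frame of factors with
#'   rownames = sample ids.
#' @param terms character vector of model terms, in testing order.
#' @param permutations number of permutations (default 999); 0 skips
#'   p-values (all `NA`).
#' @param seed optional integer seed for a reproducible permutation stream.
#' @param strata optional factor restricting permutations to within-stratum
#'   exchanges.
#' @return data.frame of class `coral_permanova` with one row per term plus
#'   `Residual` and `Total`: columns `term`, `df`, `SS`, `F`, `R2`, `p`.
#'   Term R2 values and the residual R2 sum to 1.
#' @examples
#' y <- c(0, 1, 1, 2)
#' d <- as.matrix(dist(y))
#' dimnames(d) <- list(letters[1:4], letters[1:4])
#' md <- data.frame(g = c("A", "A", "B", "B"), row.names = letters[1:4])
#' permanova(d, md, "g", permutations = 99, seed = 1)  # F = 2, as in ANOVA
#' @export
permanova <- function(d, metadata, terms, permutations = 999, seed = NULL,
                      strata = NULL) {
  d <- as.matrix(d)
  samples <- if (inherits(metadata, "coral_metadata")) metadata$samples else metadata
  if (!is.null(rownames(d)) && !is.null(rownames(samples))) {
    if (!all(rownames(d) %in% rownames(samples)))
      stop("samples in distance matrix missing from metadata")
    samples <- samples[rownames(d), , drop = FALSE]
  }
  n <- nrow(d)
  G <- gower_center(d)
  ss_total <- sum(diag(G))

  ## cumulative projectors; H0 = intercept-only
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  H_prev <- matrix(1 / n, n, n)
  Hdiff <- vector("list", length(terms))
  df <- integer(length(terms))
  for (k in seq_along(terms)) {
    X <- cbind(X, term_indicators(samples, terms[k]))
    qx <- qr(X)
    rk <- qx$rank
    if (rk == rank_prev)
      stop("term '", terms[k], "' is aliased with preceding terms (zero df)")
    Q <- qr.Q(qx)[, seq_len(rk), drop = FALSE]
    H <- tcrossprod(Q)
    Hdiff[[k]] <- H - H_prev
    df[k] <- rk - rank_prev
    H_prev <- H; rank_prev <- rk
  }
  H_res <- diag(n) - H_prev
  df_res <- n - rank_prev
  if (df_res <= 0) stop("no residual degrees of freedom")

  ss <- vapply(Hdiff, function(h) sum(h * G), numeric(1))
  ss_res <- sum(H_res * G)
  Fobs <- (ss / df) / (ss_res / df_res)

  pvals <- rep(NA_real_, length(terms))
  if (permutations > 0) {
    exceed <- integer(length(terms))
    perm_fun <- make_permuter(n, strata)
    with_seed(seed, {
      for (b in seq_len(permutations)) {
        p <- perm_fun()
        Gp <- G[p, p]
        ssp <- vapply(Hdiff, function(h) sum(h * Gp), numeric(1))
        ssr <- sum(H_res * Gp)
        Fp <- (ssp / df) / (ssr / df_res)
        exceed <- exceed + (Fp >= Fobs)
      }
    })
    pvals <- (1 + exceed) / (1 + permutations)
  }

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1L),
    SS = c(ss, ss_res, ss_total),
    F = c(Fobs, NA, NA),
    R2 = c(ss, ss_res, ss_total) / ss_total,
    p = c(pvals, NA, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coral_permanova", "data.frame")
  attr(out, "permutations") <- permutations
  out
}

## Permutation generator, optionally restricted to within-stratum exchanges.
make_permuter <- function(n, strata = NULL) {
  if (is.null(strata)) return(function() sample.int(n))
  strata <- as.factor(strata)
  idx <- split(seq_len(n), strata)
  function() {
    p <- seq_len(n)
    for (ii in idx) p[ii] <- ii[sample.int(length(ii))]
    p
  }
}

#' Pairwise post-hoc PERMANOVA with Holm correction
#'
#' One-factor PERMANOVA restricted to each pair of levels of `factor_`, with
#' sequential Bonferroni (Holm) adjustment of the permutation p-values
#' across all pairs.
#'
#' @param d distance matrix with sample dimnames.
#' @param factor_ factor of group labels, one per sample of `d`.
#' @param permutations permutations per pairwise test (default 999).
#' @param seed optional integer seed.
#' @return data.frame with columns `pair`, `level1`, `level2`, `df`, `F`,
#'   `R2`, `p`, `p_adj`.
#' @export
pairwise_permanova <- function(d, factor_, permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  f <- as.factor(factor_)
  if (nlevels(f) < 2) stop("factor must have >= 2 levels")
  small <- table(f) < 2
  if (any(small)) stop("level with < 2 samples: ",
                       paste(names(which(small)), collapse = ", "))
  pairs <- utils::combn(levels(f), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    lv <- pairs[, k]
    keep <- f %in% lv
    dk <- d[keep, keep, drop = FALSE]
    md <- data.frame(g = droplevels(f[keep]), row.names = rownames(dk))
    fit <- permanova(dk, md, "g", permutations = permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    data.frame(pair = paste(lv[1], "vs", lv[2]),
               level1 = lv[1], level2 = lv[2],
               df = fit$df[1], F = fit$F[1], R2 = fit$R2[1], p = fit$p[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p)
  out
}

#' Sequential Bonferroni (Holm) adjustment
#'
#' Step-down correction: order the m p-values ascending, multiply the i-th
#' by (m - i + 1), and enforce monotonicity by running maximum, capping at 1.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "holm")
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371.0)
}

#' Distance-decay table: dissimilarity vs geographic distance
#'
#' For each host genus and each unordered pair of distinct sites, the mean
#' and standard error of the Bray-Curtis dissimilarities over all
#' cross-site sample pairs of that genus, together with the great-circle
#' distance between the sites.
#'
#' @param d Bray-Curtis matrix with sample dimnames.
#' @param metadata `coral_metadata` with site coordinates.
#' @return data.frame with columns `genus`, `site1`, `site2`, `distance_km`,
#'   `mean_bc`, `se_bc`, `n_pairs`; one row per genus x site pair.  Pairs
#'   where the genus is missing at a site are omitted with a warning.
#' @export
distance_decay_table <- function(d, metadata) {
  d <- as.matrix(d)
  samples <- metadata$samples[rownames(d), , drop = FALSE]
  sites <- metadata$sites
  if (is.null(sites)) stop("metadata has no site coordinates")
  site_lv <- levels(samples$site)
  pairs <- utils::combn(site_lv, 2)
  rows <- list()
  for (g in levels(samples$genus)) {
    for (k in seq_len(ncol(pairs))) {
      s1 <- pairs[1, k]; s2 <- pairs[2, k]
      i1 <- which(samples$genus == g & samples$site == s1)
      i2 <- which(samples$genus == g & samples$site == s2)
      if (!length(i1) || !length(i2)) {
        warning("genus ", g, " absent at site ",
                if (!length(i1)) s1 else s2, "; pair omitted")
        next
      }
      v <- as.vector(d[i1, i2, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        genus = g, site1 = s1, site2 = s2,
        distance_km = haversine_km(sites[s1, "lat"], sites[s1, "lon"],
                                   sites[s2, "lat"], sites[s2, "lon"]),
        mean_bc = mean(v), se_bc = sd(v) / sqrt(length(v)),
        n_pairs = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

## Sequential (Type-I) OLS ANOVA via cumulative QR projections.
## Returns df, SS, F per term plus residual df/SS; used by ancova_mc where
## thousands of refits make lm() overhead matter.
seq_anova <- function(y, term_cols) {
  n <- length(y)
  X <- matrix(1, n, 1)
  rank_prev <- 1L
  fit_prev <- rep(mean(y), n)
  ss <- numeric(length(term_cols)); df <- integer(length(term_cols))
  for (k in seq_along(term_cols)) {
    X <- cbind(X, term_cols[[k]])
    qx <- qr(X)
    fit <- qr.fitted(qx, y)
    ss[k] <- sum((fit - fit_prev)^2)
    df[k] <- qx$rank - rank_prev
    rank_prev <- qx$rank; fit_prev <- fit
  }
  ss_res <- sum((y - fit_prev)^2)
  df_res <- n - rank_prev
  list(df = df, ss = ss, df_res = df_res, ss_res = ss_res,
       F = (ss / df) / (ss_res / df_res))
}

#' Monte-Carlo ANCOVA of distance decay
#'
#' Ordinary least squares of log mean dissimilarity on log geographic
#' distance (covariate), host genus (factor), and their interaction, fitted
#' sequentially in that order.  Reported per term: degrees of freedom, F,
#' and effect size eta-squared (`SS_term / SS_total`).  Because the
#' genus x site-pair means are not independent, significance comes from
#' Monte-Carlo simulation: the (distance, genus) rows are shuffled against
#' the dissimilarity values (jointly by default), the model refitted, and
#' each term's p-value is the proportion of shuffled datasets whose F meets
#' or exceeds the observed one.
#'
#' @param ddt distance-decay table from [distance_decay_table()].
#' @param permutations Monte-Carlo replicates (default 999).
#' @param seed optional integer seed.
#' @param shuffle `"joint"` (default; distance and genus shuffled as rows)
#'   or `"independent"` (each shuffled separately).
#' @return data.frame of class `coral_ancova` with rows Distance, Genus,
#'   Distance:Genus, Residual: columns `term`, `df`, `F`, `eta2`, `p`.
#'   Also carries attribute `r_squared` (model R2).
#' @export
ancova_mc <- function(ddt, permutations = 999, seed = NULL,
                      shuffle = c("joint", "independent")) {
  shuffle <- match.arg(shuffle)
  if (any(ddt$mean_bc <= 0) || any(ddt$distance_km <= 0))
    stop("log transform requires positive dissimilarities and distances")
  y <- log(ddt$mean_bc)
  x <- log(ddt$distance_km)
  g <- factor(ddt$genus)
  n <- length(y)
  build_terms <- function(x, g) {
    Xg <- stats::model.matrix(~ 0 + g)
    list(matrix(x, ncol = 1), Xg, Xg * x)
  }
  obs <- seq_anova(y, build_terms(x, g))
  if (n <= sum(obs$df) + 1) stop("fewer rows than model parameters")
  ss_total <- sum(obs$ss) + obs$ss_res

  pvals <- rep(NA_real_, 3)
  if (permutations > 0) {
    exceed <- integer(3)
    with_seed(seed, {
      for (b in seq_len(permutations)) {
        if (shuffle == "joint") {
          p <- sample.int(n); xs <- x[p]; gs <- g[p]
        } else {
          xs <- x[sample.int(n)]; gs <- g[sample.int(n)]
        }
        Fp <- seq_anova(y, build_terms(xs, gs))$F
        exceed <- exceed + (Fp >= obs$F)
      }
    })
    pvals <- exceed / permutations
  }

  out <- data.frame(
    term = c("Distance", "Genus", "Distance:Genus", "Residual"),
    df = c(obs$df, obs$df_res),
    F = c(obs$F, NA),
    eta2 = c(obs$ss, obs$ss_res) / ss_total,
    p = c(pvals, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("coral_ancova", "data.frame")
  attr(out, "r_squared") <- sum(obs$ss) / ss_total
  attr(out, "slope") <- unname(stats::coef(lm(y ~ x))[2])
  out
}
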