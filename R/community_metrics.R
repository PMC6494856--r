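## Bray-Curtis dissimilarity, core-microbiome detection, class-level
## profiles, and SIMPER decomposition of between-group dissimilarity.

#' Bray-Curtis dissimilarity matrix
#'
#' `d[a,b] = sum |x_a - x_b| / sum (x_a + x_b)` over OTUs, computed on
#' (normalized) abundances.  Values are in \[0, 1\]: 0 for identical
#' communities, 1 for disjoint ones.
#'
#' @param x `coral_norm` object or samples x OTUs abundance matrix.
#' @return symmetric matrix of class `coral_dist` with sample dimnames and
#'   attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(x) {
  m <- abundance_matrix(x)
  if (any(rowSums(m) <= 0))
    stop("zero-sum sample (Bray-Curtis undefined): ",
         paste(rownames(m)[rowSums(m) <= 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  structure(d, metric = "bray-curtis", class = c("coral_dist", "matrix", "array"))
}

#' Per-group OTU prevalence
#'
#' Prevalence is the fraction of a group's samples in which an OTU is present
#' (raw count > 0); presence/absence is judged on raw counts, before any
#' normalization.
#'
#' @param counts samples x OTUs count matrix.
#' @param groups factor (or vector) of group labels, one per sample.
#' @return matrix groups x OTUs of prevalences in \[0, 1\].
#' @export
prevalence <- function(counts, groups) {
  groups <- as.factor(groups)
  if (length(groups) != nrow(counts))
    stop("groups must have one label per sample")
  if (any(table(groups) == 0))
    stop("empty group: ", paste(levels(groups)[table(groups) == 0], collapse = ", "))
  pres <- counts > 0
  out <- t(vapply(levels(groups),
                  function(g) colMeans(pres[groups == g, , drop = FALSE]),
                  numeric(ncol(counts))))
  rownames(out) <- levels(groups)
  out
}

#' Core-microbiome detection by prevalence threshold
#'
#' An OTU belongs to a group's core when its prevalence strictly exceeds
#' `threshold` (so exactly 95% at the default threshold is excluded).
#' Within each group the class-level relative abundances of the core OTUs
#' are computed from normalized abundances and renormalized to sum to one.
#'
#' @param counts samples x OTUs count matrix (presence/absence source).
#' @param groups factor of group labels (typically host genus).
#' @param threshold prevalence threshold in (0, 1); default 0.95.
#' @param normalized optional `coral_norm` (or matrix) for class abundance
#'   profiles of the core; if omitted, raw counts are used.
#' @param taxonomy optional `coral_taxonomy` for class aggregation.
#' @return object of class `coral_core`: named list per group with elements
#'   `prevalence` (named vector), `core` (OTU ids), and `class_profile`
#'   (named vector summing to 1, or NULL without a core/taxonomy).
#' @export
core_microbiome <- function(counts, groups, threshold = 0.95,
                            normalized = NULL, taxonomy = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  groups <- as.factor(groups)
  prev <- prevalence(counts, groups)
  ab <- if (is.null(normalized)) counts else abundance_matrix(normalized)
  out <- lapply(levels(groups), function(g) {
    p <- prev[g, ]
    core <- colnames(counts)[p > threshold]
    if (!length(core))
      warning("empty core set for group ", g, " at threshold ", threshold)
    profile <- NULL
    if (length(core) && !is.null(taxonomy)) {
      sub <- ab[groups == g, core, drop = FALSE]
      tot <- colSums(sub)
      cls <- taxonomy_class(taxonomy, core)
      profile <- tapply(tot, cls, sum)
      profile <- profile / sum(profile)
      profile <- sort(c(profile), decreasing = TRUE)
    }
    list(group = g, prevalence = p, core = core, class_profile = profile)
  })
  names(out) <- levels(groups)
  structure(out, threshold = threshold, class = "coral_core")
}

#' @export
print.coral_core <- function(x, ...) {
  cat("coral_core (prevalence >", attr(x, "threshold"), "):\n")
  for (g in names(x)) {
    cat(" ", g, ":", length(x[[g]]$core), "core OTUs\n")
    if (!is.null(x[[g]]$class_profile)) {
      pr <- x[[g]]$class_profile
      cat("    ", paste(sprintf("%s=%.2f", names(pr), pr), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Class-level relative abundance profiles
#'
#' Aggregates (normalized) abundances to taxonomic class within each group
#' and renormalizes so each group's class proportions sum to one.
#'
#' @param x `coral_norm` or abundance matrix.
#' @param taxonomy `coral_taxonomy`.
#' @param groups factor of group labels, one per sample.
#' @return matrix groups x classes of proportions (rows sum to 1).
#' @export
class_abundance_profile <- function(x, taxonomy, groups) {
  m <- abundance_matrix(x)
  groups <- as.factor(groups)
  if (length(groups) != nrow(m)) stop("groups must have one label per sample")
  cls <- taxonomy_class(taxonomy, colnames(m))
  classes <- sort(unique(cls))
  out <- t(vapply(levels(groups), function(g) {
    tot <- colSums(m[groups == g, , drop = FALSE])
    v <- vapply(classes, function(cc) sum(tot[cls == cc]), numeric(1))
    v / sum(v)
  }, numeric(length(classes))))
  dimnames(out) <- list(levels(groups), classes)
  out
}

#' SIMPER: decomposition of between-group dissimilarity
#'
#' For a pair of groups, the contribution of OTU i is the average over all
#' cross-group sample pairs (a, b) of `|x_ai - x_bi| / sum_k (x_ak + x_bk)`.
#' Contributions are non-negative and sum exactly to the mean between-group
#' Bray-Curtis dissimilarity.  When a taxonomy is supplied, per-OTU rows are
#' additionally aggregated (summed) at the taxonomic level of class.
#'
#' @param x `coral_norm` or abundance matrix (same matrix used for
#'   [bray_curtis()], for internal consistency).
#' @param groups factor of group labels.
#' @param pair character vector of two group labels to compare.
#' @param taxonomy optional `coral_taxonomy` for class aggregation.
#' @return object of class `coral_simper`: list with `otu` (data.frame otu,
#'   class, contribution, percent, ordered by decreasing contribution),
#'   `class` (data.frame class, contribution, percent, or NULL), and
#'   `mean_dissimilarity`.
#' @export
simper <- function(x, groups, pair, taxonomy = NULL) {
  m <- abundance_matrix(x)
  groups <- as.factor(groups)
  if (length(pair) != 2 || !all(pair %in% levels(groups)))
    stop("pair must name two levels of groups")
  ia <- which(groups == pair[1]); ib <- which(groups == pair[2])
  if (!length(ia) || !length(ib)) stop("empty group in pair")
  contrib <- numeric(ncol(m))
  for (a in ia) {
    xa <- m[a, ]
    for (b in ib) {
      xb <- m[b, ]
      denom <- sum(xa + xb)
      contrib <- contrib + abs(xa - xb) / denom
    }
  }
  contrib <- contrib / (length(ia) * length(ib))
  total <- sum(contrib)
  pct <- if (total > 0) 100 * contrib / total else rep(0, length(contrib))
  cls <- if (is.null(taxonomy)) rep(NA_character_, ncol(m))
         else taxonomy_class(taxonomy, colnames(m))
  otu_df <- data.frame(otu = colnames(m), class = cls,
                       contribution = contrib, percent = pct,
                       stringsAsFactors = FALSE)
  otu_df <- otu_df[order(-otu_df$contribution), ]
  rownames(otu_df) <- NULL
  cls_df <- NULL
  if (!is.null(taxonomy)) {
    agg <- tapply(contrib, cls, sum)
    cls_df <- data.frame(class = names(agg), contribution = c(agg),
                         percent = if (total > 0) 100 * c(agg) / total else 0,
                         stringsAsFactors = FALSE)
    cls_df <- cls_df[order(-cls_df$contribution), ]
    rownames(cls_df) <- NULL
  }
  structure(list(pair = pair, otu = otu_df, class = cls_df,
                 mean_dissimilarity = total),
            class = "coral_simper")
}

#' @export
print.coral_simper <- function(x, n = 10, ...) {
  cat("SIMPER", x$pair[1], "vs", x$pair[2],
      "| mean Bray-Curtis =", signif(x$mean_dissimilarity, 4), "\n")
  print(utils::head(if (is.null(x$class)) x$otu else x$class, n))
  invisible(x)
}
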