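#' Median-of-ratios library-size normalization
#'
#' Computes per-sample size factors by the median-of-ratios method used for
#' count libraries of unequal depth: each sample's factor is the median,
#' over a set of reference OTUs, of the ratio of its count to that OTU's
#' geometric mean across samples.  Normalized values are `counts / s_j`.
#'
#' Sparse OTU tables often contain no OTU observed in every sample, in which
#' case the classical estimator is undefined.  Two policies are exposed:
#'
#' * `"all-positive-reference"` (classical): reference set = OTUs with
#'   strictly positive counts in every sample; errors if the set is empty.
#' * `"pseudo-geomean"`: geometric means are taken over positive entries
#'   only, and each sample's median runs over the OTUs it actually contains
#'   (poscounts-style), so it is defined for any table with non-empty samples.
#'
#' @param counts samples x OTUs count matrix (see [validate_counts()]).
#' @param zero_policy `"all-positive-reference"` or `"pseudo-geomean"`.
#' @return object of class `coral_norm`: list with `values` (matrix, same
#'   shape and dimnames as `counts`) and `size_factors` (named positive
#'   vector, one per sample).
#' @examples
#' m <- rbind(s1 = c(10, 5, 2), s2 = c(20, 10, 4))
#' colnames(m) <- paste0("OTU", 1:3)
#' normalize_median_of_ratios(m)$size_factors  # (1/sqrt(2), sqrt(2))
#' @export
normalize_median_of_ratios <- function(counts,
                                       zero_policy = c("all-positive-reference",
                                                       "pseudo-geomean")) {
  zero_policy <- match.arg(zero_policy)
  validate_counts(counts)
  if (nrow(counts) < 2) stop("need >= 2 samples to normalize")
  if (zero_policy == "all-positive-reference") {
    ref <- colSums(counts > 0) == nrow(counts)
    if (!any(ref))
      stop("no OTU has positive counts in every sample; ",
           "use zero_policy = \"pseudo-geomean\"")
    g <- exp(colMeans(log(counts[, ref, drop = FALSE])))
    ratios <- sweep(counts[, ref, drop = FALSE], 2, g, "/")
    s <- apply(ratios, 1, median)
  } else {
    lg <- log(counts)
    lg[!is.finite(lg)] <- NA
    g <- exp(colMeans(lg, na.rm = TRUE))           # geomean over positive entries
    usable <- colSums(counts > 0) > 0
    s <- vapply(seq_len(nrow(counts)), function(j) {
      pos <- counts[j, ] > 0 & usable
      median(counts[j, pos] / g[pos])
    }, numeric(1))
  }
  if (any(!is.finite(s)) || any(s <= 0))
    stop("degenerate size factor for sample: ",
         paste(rownames(counts)[!is.finite(s) | s <= 0], collapse = ", "))
  names(s) <- rownames(counts)
  structure(list(values = counts / s, size_factors = s), class = "coral_norm")
}

#' @export
print.coral_norm <- function(x, ...) {
  cat("coral_norm:", nrow(x$values), "samples x", ncol(x$values), "OTUs; ",
      "size factors in [", signif(min(x$size_factors), 4), ",",
      signif(max(x$size_factors), 4), "]\n")
  invisible(x)
}

## Accept either a coral_norm or a bare matrix of abundances.
abundance_matrix <- function(x) {
  if (inherits(x, "coral_norm")) x$values
  else if (is.matrix(x)) x
  else stop("expected a coral_norm object or a samples x OTUs matrix")
}
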