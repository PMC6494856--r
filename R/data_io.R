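## Data model and readers/writers.
##
## Canonical orientation throughout the package: samples are rows, OTUs are
## columns.  A count table is a plain non-negative integer matrix with unique
## sample rownames and OTU colnames; metadata is a list with a per-sample
## data.frame and a per-site coordinate data.frame.

#' Validate an OTU count table
#'
#' Checks the invariants assumed by every downstream stage: unique sample and
#' OTU identifiers, non-negative integral counts, and no empty (all-zero)
#' sample.
#'
#' @param counts numeric matrix, samples x OTUs, with dimnames.
#' @return the matrix, invisibly, after validation.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  zs <- rowSums(counts) == 0
  if (any(zs))
    stop("empty sample (all-zero counts): ", paste(rownames(counts)[zs], collapse = ", "))
  invisible(counts)
}

#' Read an OTU count table
#'
#' Reads a samples x OTUs count matrix from either a TSV file (first column
#' sample id, header row of OTU ids) or a BIOM-JSON v1.0 file (dense or
#' sparse; sparse tables are expanded).  BIOM stores observations (OTUs) as
#' rows; the result is always returned in the package's canonical
#' samples-as-rows orientation.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`.
#' @param transpose for TSV input whose first column holds OTU ids (OTUs as
#'   rows), set `TRUE` to transpose into canonical orientation.
#' @return validated integer matrix, samples x OTUs.
#' @export
read_count_table <- function(path, format = c("tsv", "biom-json"), transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("malformed header: need id column plus >=1 OTU column")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    rownames(m) <- ids
    if (transpose) m <- t(m)
  } else {
    b <- biomformat::read_biom(path)
    m <- t(as(biomformat::biom_data(b), "matrix"))  # biom rows = observations
  }
  storage.mode(m) <- "double"
  validate_counts(m)
  m
}

#' Write an OTU count table
#'
#' Inverse of [read_count_table()]: TSV with a leading `sample` column, or
#' BIOM-JSON v1.0 (observations as rows, per the format).
#'
#' @param counts samples x OTUs matrix.
#' @param path output path.
#' @param format `"tsv"` or `"biom-json"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "tsv") {
    df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- biomformat::make_biom(data = t(counts))
    biomformat::write_biom(b, path)
  }
  invisible(path)
}

#' Read sample metadata and site coordinates
#'
#' Expects a TSV with columns `sample`, `genus`, `species`, `site`, `time`,
#' and site coordinates either inline (`lat`, `lon` columns) or in a separate
#' TSV with columns `site`, `lat`, `lon`.  Factor levels are recorded in
#' first-appearance order, which fixes the ordering used for permutation
#' streams and tie-breaking downstream.
#'
#' @param path metadata TSV path.
#' @param sites_path optional site-coordinate TSV path.
#' @param counts optional count matrix to cross-validate sample ids against.
#' @return object of class `coral_metadata`: list with `samples` (data.frame
#'   of factors, rownames = sample ids) and `sites` (data.frame site/lat/lon).
#' @export
read_metadata <- function(path, sites_path = NULL, counts = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "genus", "species", "site", "time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  sites <- NULL
  if (!is.null(sites_path)) {
    sites <- read.delim(sites_path, check.names = FALSE, stringsAsFactors = FALSE)
  } else if (all(c("lat", "lon") %in% names(df))) {
    sites <- unique(df[, c("site", "lat", "lon")])
  }
  make_metadata(df[need], sites = sites, counts = counts)
}

#' Assemble and validate metadata from data frames
#'
#' Programmatic constructor behind [read_metadata()]; useful when metadata is
#' built in code (e.g. by the simulator).
#'
#' @param samples data.frame with columns sample, genus, species, site, time.
#' @param sites optional data.frame with columns site, lat, lon.
#' @param counts optional count matrix to cross-validate sample ids against.
#' @return `coral_metadata` object.
#' @export
make_metadata <- function(samples, sites = NULL, counts = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample id in metadata: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))
  ## species -> genus must be a function
  sg <- unique(samples[, c("species", "genus")])
  dup <- sg$species[duplicated(sg$species)]
  if (length(dup))
    stop("species mapped to two genera: ", paste(unique(dup), collapse = ", "))
  for (v in c("genus", "species", "site", "time"))
    samples[[v]] <- factor(samples[[v]], levels = unique(as.character(samples[[v]])))
  rownames(samples) <- samples$sample
  if (!is.null(counts)) {
    only_counts <- setdiff(rownames(counts), samples$sample)
    if (length(only_counts))
      stop("sample in counts but not metadata: ", paste(only_counts, collapse = ", "))
    only_meta <- setdiff(samples$sample, rownames(counts))
    if (length(only_meta))
      stop("sample in metadata but not counts: ", paste(only_meta, collapse = ", "))
    samples <- samples[rownames(counts), , drop = FALSE]
  }
  if (!is.null(sites)) {
    sites <- as.data.frame(sites, stringsAsFactors = FALSE)
    if (!all(c("site", "lat", "lon") %in% names(sites)))
      stop("site table needs columns site, lat, lon")
    if (anyDuplicated(sites$site)) stop("duplicate site in coordinate table")
    if (any(!is.finite(sites$lat)) || any(abs(sites$lat) > 90))
      stop("latitude out of range")
    if (any(!is.finite(sites$lon)) || any(abs(sites$lon) > 180))
      stop("longitude out of range")
    miss <- setdiff(levels(samples$site), sites$site)
    if (length(miss)) stop("site without coordinates: ", paste(miss, collapse = ", "))
    rownames(sites) <- sites$site
  }
  structure(list(samples = samples, sites = sites), class = "coral_metadata")
}

#' @export
print.coral_metadata <- function(x, ...) {
  s <- x$samples
  cat("coral_metadata:", nrow(s), "samples |",
      nlevels(s$genus), "genera,", nlevels(s$species), "species,",
      nlevels(s$site), "sites,", nlevels(s$time), "time points\n")
  if (!is.null(x$sites)) {
    cat("sites:\n"); print(x$sites, ...)
  }
  invisible(x)
}

#' Read a taxonomy map
#'
#' TSV with columns `otu` and `lineage`, the lineage a QIIME-style string
#' (`"k__Bacteria; p__...; c__...; ..."`).  Missing or empty ranks are
#' rendered `"unclassified_<parent>"` so class-level aggregation conserves
#' total abundance instead of dropping reads.
#'
#' @param path taxonomy TSV path.
#' @param otu_ids optional OTU ids that must all be resolvable; unknown OTUs
#'   are added with class `"unclassified"`.
#' @return data.frame of class `coral_taxonomy` with columns `otu`,
#'   `lineage`, `class`.
#' @export
read_taxonomy <- function(path, otu_ids = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("otu", "lineage") %in% names(df)))
    stop("taxonomy needs columns otu, lineage")
  make_taxonomy(df$otu, df$lineage, otu_ids = otu_ids)
}

#' Build a taxonomy map from lineage strings
#'
#' @param otu OTU ids.
#' @param lineage QIIME-style lineage strings.
#' @param otu_ids optional full OTU universe (see [read_taxonomy()]).
#' @return `coral_taxonomy` data.frame.
#' @export
make_taxonomy <- function(otu, lineage, otu_ids = NULL) {
  if (anyDuplicated(otu)) stop("duplicate OTU in taxonomy")
  cls <- vapply(lineage, lineage_class, character(1), USE.NAMES = FALSE)
  df <- data.frame(otu = as.character(otu), lineage = as.character(lineage),
                   class = cls, stringsAsFactors = FALSE)
  if (!is.null(otu_ids)) {
    extra <- setdiff(otu_ids, df$otu)
    if (length(extra))
      df <- rbind(df, data.frame(otu = extra, lineage = "", class = "unclassified"))
    df <- df[match(otu_ids, df$otu), , drop = FALSE]
  }
  rownames(df) <- df$otu
  class(df) <- c("coral_taxonomy", "data.frame")
  df
}

## Extract the class rank from one QIIME lineage string; fall back to
## unclassified_<nearest named parent>.
lineage_class <- function(lin) {
  if (is.na(lin) || !nzchar(lin)) return("unclassified")
  parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
  val <- function(prefix) {
    hit <- grep(paste0("^", prefix, "__"), parts, value = TRUE)
    if (!length(hit)) return("")
    sub(paste0("^", prefix, "__"), "", hit[1])
  }
  cls <- val("c")
  if (nzchar(cls)) return(cls)
  for (r in c("p", "k")) {
    parent <- val(r)
    if (nzchar(parent)) return(paste0("unclassified_", parent))
  }
  "unclassified"
}

#' Look up taxonomic class for OTU ids
#'
#' @param taxonomy `coral_taxonomy` object.
#' @param otu_ids OTU ids.
#' @return character vector of class names (`"unclassified"` when unknown).
#' @export
taxonomy_class <- function(taxonomy, otu_ids) {
  i <- match(otu_ids, taxonomy$otu)
  out <- taxonomy$class[i]
  out[is.na(i)] <- "unclassified"
  out
}

#' Write a result table or list to CSV or JSON
#'
#' Every result type in the package is either a data.frame (term tables,
#' SIMPER tables, distance-decay tables) or a list of atomic pieces (core
#' sets, network summaries); both serialize losslessly.
#'
#' @param obj data.frame or list.
#' @param path output path.
#' @param format `"csv"` (data.frames only; RFC-4180 quoting) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(obj)) stop("CSV output requires a data.frame")
    write.csv(obj, path, row.names = FALSE)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read a result written by [write_results()]
#'
#' @param path input path.
#' @param format `"csv"` or `"json"`.
#' @return data.frame (csv) or list/data.frame (json).
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  else jsonlite::fromJSON(path)
}
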