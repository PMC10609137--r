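# Readers/writers for the external formats plus the core shared types.
#
# Internal conventions:
#   * feature tables are integer matrices, samples as rows, taxa as columns;
#   * lipid panels are numeric matrices (samples x lipids, ug/g dry mass)
#     with an "unit" attribute and a per-lipid unsaturation class;
#   * trees are ape "phylo" objects, rooted and binary;
#   * sample metadata is a data.frame keyed by sample_id;
#   * distance matrices are symmetric numeric matrices with zero diagonal.

#' Validate a feature table
#'
#' @param counts numeric matrix, samples x taxa, with dimnames.
#' @param drop_empty drop all-zero samples (with a warning) instead of failing.
#' @return validated integer matrix.
#' @export
validate_feature_table <- function(counts, drop_empty = TRUE) {
  stopifnot_named_matrix(counts, "feature table")
  if (anyDuplicated(rownames(counts))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon identifiers")
  if (any(is.na(counts))) stop("missing values in feature table")
  if (any(counts < 0)) stop("negative counts in feature table")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer counts in feature table")
  storage.mode(counts) <- "integer"
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    if (!drop_empty) stop("all-zero sample rows: ",
                          paste(rownames(counts)[empty], collapse = ", "))
    warning("dropping ", sum(empty), " all-zero sample(s): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) == 0) stop("no samples left in feature table")
  counts
}

#' Read an ASV count table from TSV
#'
#' Expects a header row of taxon identifiers and a first column of sample
#' identifiers (set `transpose = TRUE` when the file stores taxa as rows).
#'
#' @param path TSV file path.
#' @param transpose logical; file is taxa x samples.
#' @return integer matrix, samples x taxa.
#' @export
read_feature_table <- function(path, transpose = FALSE) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(as.numeric(m))) & !is.na(m),
                 arr.ind = TRUE)
    stop("non-numeric cell at row '", rownames(m)[bad[1, 1]],
         "', column '", colnames(m)[bad[1, 2]], "'")
  }
  if (transpose) m <- t(m)
  validate_feature_table(m)
}

#' Write a feature table as TSV
#' @param counts samples x taxa matrix.
#' @param path output path.
#' @export
write_feature_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from Newick
#'
#' The tree must carry branch lengths. Internal multifurcations (commonly a
#' trifurcating root) are optionally resolved into binary nodes by inserting
#' zero-length edges, which downstream balance construction requires.
#'
#' @param path Newick file path.
#' @param resolve_multifurcations insert zero-length edges to binarize.
#' @param missing_lengths "error" (default) or "zero".
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path, resolve_multifurcations = TRUE,
                        missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file: ", path)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error") stop("tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length))) {
    if (missing_lengths == "error") stop("tree has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree)) {
    if (!resolve_multifurcations)
      stop("tree contains multifurcations; set resolve_multifurcations = TRUE")
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
    message("resolved multifurcation(s) with zero-length edges")
  }
  tree
}

#' Write a tree as Newick
#' @param tree `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Unsaturation class of fatty-acid names
#'
#' Classifies shorthand lipid names ("16:0", "18:1n9", "18:3n6", "18:3n3")
#' into saturated / omega-9 / omega-6 / omega-3 / other.
#'
#' @param lipids character vector of lipid names.
#' @return character vector of classes.
#' @export
lipid_unsaturation_class <- function(lipids) {
  cls <- rep("other", length(lipids))
  cls[grepl(":\\d+n9$", lipids)] <- "omega9"
  cls[grepl(":\\d+n6$", lipids)] <- "omega6"
  cls[grepl(":\\d+n3$", lipids)] <- "omega3"
  cls[grepl(":0$", lipids)] <- "saturated"
  names(cls) <- lipids
  cls
}

#' Read a fecal lipid panel from CSV
#'
#' Concentrations are in micrograms per gram of fecal dry mass. Readings
#' below the lower limit of quantification, encoded by a sentinel string
#' (default `"<LLOQ"`; empty cells are treated the same way), are replaced
#' by a fixed small concentration (default 0.001).
#'
#' @param path CSV path; first column sample identifiers, remaining columns
#'   lipids.
#' @param lloq_sentinel sentinel string marking below-LLOQ cells.
#' @param lloq_value substituted concentration.
#' @return numeric matrix samples x lipids with attributes `unit` and
#'   `class` (per-lipid unsaturation class).
#' @export
read_lipid_panel <- function(path, lloq_sentinel = "<LLOQ",
                             lloq_value = 0.001) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   row.names = 1, stringsAsFactors = FALSE,
                   colClasses = "character")
  m <- as.matrix(df)
  m[m == lloq_sentinel | m == "" | is.na(m)] <- as.character(lloq_value)
  conc <- suppressWarnings(apply(m, 2, as.numeric))
  if (!is.matrix(conc)) conc <- matrix(conc, nrow = nrow(m))
  dimnames(conc) <- dimnames(m)
  if (any(is.na(conc))) {
    bad <- which(is.na(conc), arr.ind = TRUE)
    stop("unparseable concentration at row '", rownames(conc)[bad[1, 1]],
         "', column '", colnames(conc)[bad[1, 2]], "'")
  }
  if (any(conc < 0)) stop("negative lipid concentration")
  attr(conc, "unit") <- "ug/g dry mass"
  attr(conc, "lipid_class") <- lipid_unsaturation_class(colnames(conc))
  conc
}

#' Write a lipid panel as CSV
#' @param panel samples x lipids matrix.
#' @param path output path.
#' @export
write_lipid_panel <- function(panel, path) {
  df <- data.frame(sample_id = rownames(panel), panel, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

GROUP_LEVELS <- c("Control", "IBS-D", "IBS-M", "IBS-C")

#' Validate sample metadata
#'
#' Requires columns `group` (Control / IBS-D / IBS-M / IBS-C),
#' `hfcs_monthly` (grams per month), `income_bracket`, `marital_status`,
#' `alcohol`, `occupants`; derives the binary `ibs_status`.
#'
#' @param df data.frame with a `sample_id` column or row names.
#' @return validated data.frame with factor `group` and `ibs_status`.
#' @export
validate_sample_metadata <- function(df) {
  if (!"sample_id" %in% names(df)) df$sample_id <- rownames(df)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample identifiers")
  needed <- c("group", "hfcs_monthly", "income_bracket", "marital_status",
              "alcohol", "occupants")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$group %in% GROUP_LEVELS))
    stop("group must be one of ", paste(GROUP_LEVELS, collapse = ", "))
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df$ibs_status <- factor(ifelse(df$group == "Control", "Control", "IBS"),
                          levels = c("Control", "IBS"))
  if (any(df$hfcs_monthly < 0)) stop("negative HFCS consumption")
  if (any(df$occupants < 1)) stop("occupants must be >= 1")
  rownames(df) <- df$sample_id
  df
}

#' Read sample metadata from TSV
#' @param path TSV path with a `sample_id` column.
#' @return validated metadata data.frame.
#' @export
read_sample_metadata <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_sample_metadata(df)
}

#' Write sample metadata as TSV
#' @param metadata data.frame.
#' @param path output path.
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a distance matrix
#' @param m square numeric matrix with matching dimnames.
#' @return the matrix, diagonal forced to exactly zero.
#' @export
validate_distance_matrix <- function(m) {
  stopifnot_named_matrix(m, "distance matrix")
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching labels")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix not symmetric")
  diag(m) <- 0
  m
}

#' Write a labeled distance matrix as TSV
#' @param m distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled distance matrix from TSV
#' @param path TSV path.
#' @return validated distance matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = 1)
  validate_distance_matrix(as.matrix(df))
}

# One multivariate hypergeometric draw: `depth` reads sampled without
# replacement from a vector of per-taxon read counts.
rmvhyper_once <- function(counts, depth) {
  m <- length(counts)
  out <- integer(m)
  remaining <- sum(counts)
  need <- depth
  for (j in seq_len(m)) {
    if (need == 0) break
    white <- counts[j]
    black <- remaining - white
    k <- rhyper(1, white, black, need)
    out[j] <- k
    need <- need - k
    remaining <- black
  }
  out
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples with fewer than `depth` total
#' reads are dropped with a warning.
#'
#' @param counts samples x taxa integer matrix.
#' @param depth target reads per sample (default 54000).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return samples x taxa integer matrix; every row sums to `depth`.
#' @export
rarefy <- function(counts, depth = 54000, seed = NULL) {
  stopifnot(depth >= 1)
  totals <- rowSums(counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples retained at depth ", depth)
  if (any(!keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[!keep], collapse = ", "))
  sub <- counts[keep, , drop = FALSE]
  local_seed(seed, {
    out <- t(apply(sub, 1, rmvhyper_once, depth = depth))
  })
  dimnames(out) <- dimnames(sub)
  storage.mode(out) <- "integer"
  out
}
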