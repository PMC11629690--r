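# Cell featurization: the four omics modalities (EXP, PES, MUT, CNV).
# Profiles are stored as a genes-x-cells matrix wrapped with its modality so
# feature order is shared, by construction, across all cells of a dataset.

.MODALITIES <- c("EXP", "PES", "MUT", "CNV")

#' Construct a set of cell profiles
#'
#' @param values Numeric matrix, features (genes or pathways) x cells, with
#'   row and column names.
#' @param modality One of `"EXP"`, `"PES"`, `"MUT"`, `"CNV"`.
#' @return An object of class `cell_profiles`.
#' @export
cell_profiles <- function(values, modality) {
  modality <- match.arg(modality, .MODALITIES)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("cell profile matrix needs row (feature) and column (cell) names")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate feature ids: ", paste(dups, collapse = ", "))
  }
  if (!all(is.finite(values))) stop("non-finite values in ", modality, " profiles")
  if (modality == "MUT" && !all(values %in% c(0, 1))) stop("MUT profiles must be binary")
  structure(list(values = values, modality = modality,
                 feature_names = rownames(values), cell_ids = colnames(values)),
            class = "cell_profiles")
}

#' @export
print.cell_profiles <- function(x, ...) {
  cat("<cell_profiles> ", x$modality, ": ", nrow(x$values), " features x ",
      ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Load an omics matrix from a TSV file
#'
#' Expects genes as rows and cells as columns, a header row of cell ids, and
#' a first column of gene ids. Row order is preserved as feature order.
#'
#' @param path Path to the TSV file.
#' @param modality One of `"EXP"`, `"PES"`, `"MUT"`, `"CNV"`.
#' @return A `cell_profiles` object (one profile per column).
#' @export
load_omics_matrix <- function(path, modality) {
  modality <- match.arg(modality, .MODALITIES)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids in ", path, ": ", paste(dups, collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (modality == "MUT" && (is.logical(col) || is.character(col))) next
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0L) {
      stop("non-numeric value in ", path, " at row ", bad[1L],
           " (gene ", gene_ids[bad[1L]], "), column '", colnames(vals)[j], "'")
    }
    vals[[j]] <- num
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  if (modality == "MUT") return(encode_mutation(m))
  cell_profiles(m, modality)
}

#' Read a gene-set collection from a GMT file
#'
#' @param path Path to a GMT file (set name, description, then gene ids,
#'   tab-separated).
#' @return An object of class `gene_set_collection`: a named list of gene-id
#'   character vectors.
#' @export
read_gene_sets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0L)) stop("empty gene set(s) in ", path)
  structure(sets, class = "gene_set_collection")
}

#' Single-sample pathway enrichment scores
#'
#' For each cell, expression is z-scored across genes within the cell and a
#' pathway's score is the mean z-score over the pathway's genes present in
#' the profile. Cheap, deterministic, and invariant to gene order. Sets with
#' no gene overlap are dropped with a warning.
#'
#' @param exp A `cell_profiles` object with modality `"EXP"`.
#' @param gene_sets A [read_gene_sets()] result or named list of gene-id
#'   vectors.
#' @return A `cell_profiles` object with modality `"PES"` (pathways x cells).
#' @export
compute_pathway_scores <- function(exp, gene_sets) {
  stopifnot(inherits(exp, "cell_profiles"))
  if (exp$modality != "EXP") stop("pathway scores are computed from EXP profiles")
  present <- lapply(gene_sets, function(gs) intersect(gs, exp$feature_names))
  keep <- lengths(present) > 0L
  if (!any(keep)) stop("no gene set overlaps the expression profile gene ids")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " gene set(s) with no overlapping genes: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  }
  z <- scale(exp$values)  # column-wise: z-score within each cell
  scores <- vapply(present[keep], function(gs) colMeans(z[gs, , drop = FALSE]),
                   numeric(ncol(exp$values)))
  scores <- t(as.matrix(scores))
  if (ncol(exp$values) == 1L) scores <- matrix(scores, ncol = 1L, dimnames = list(names(present[keep]), exp$cell_ids))
  rownames(scores) <- names(present)[keep]
  colnames(scores) <- exp$cell_ids
  cell_profiles(scores, "PES")
}

#' Encode a raw mutation table as binary profiles
#'
#' Accepts 0/1 numerics, logicals, or the strings TRUE/FALSE (and T/F,
#' yes/no, case-insensitive), which are mapped to 1/0 with a message.
#'
#' @param raw Matrix or data frame, genes x cells, with dimnames.
#' @return A `cell_profiles` object with modality `"MUT"`.
#' @export
encode_mutation <- function(raw) {
  m <- as.matrix(raw)
  if (is.logical(m)) {
    m <- m + 0
  } else if (is.character(m)) {
    lo <- tolower(trimws(m))
    mapped <- ifelse(lo %in% c("true", "t", "yes", "1"), 1,
                     ifelse(lo %in% c("false", "f", "no", "0"), 0, NA))
    if (anyNA(mapped)) {
      bad <- unique(m[is.na(mapped)])
      stop("non-binary mutation entries with no mapping: ", paste(bad, collapse = ", "))
    }
    message("encode_mutation: mapped truthy strings to 0/1")
    m <- matrix(mapped, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  storage.mode(m) <- "numeric"
  if (!all(m %in% c(0, 1))) {
    bad <- unique(m[!(m %in% c(0, 1))])
    stop("non-binary mutation entries: ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  cell_profiles(m, "MUT")
}

#' Encode a copy-number table as continuous profiles
#'
#' Values (log-ratio scale assumed) pass through unchanged; a discretisation
#' threshold can be applied optionally.
#'
#' @param raw Numeric matrix or data frame, genes x cells, with dimnames.
#' @param discretize_at If non-NULL, values are mapped to sign(x) *
#'   (abs(x) >= threshold) instead of passed through.
#' @return A `cell_profiles` object with modality `"CNV"`.
#' @export
encode_cnv <- function(raw, discretize_at = NULL) {
  m <- as.matrix(raw)
  storage.mode(m) <- "numeric"
  if (!all(is.finite(m))) stop("non-finite entries in CNV table")
  if (!is.null(discretize_at)) m <- sign(m) * (abs(m) >= discretize_at)
  cell_profiles(m, "CNV")
}

#' Restrict profiles to a gene subset
#'
#' Output feature order follows the subset order; subset genes absent from
#' the profiles are dropped with a message.
#'
#' @param profiles A `cell_profiles` object.
#' @param subset Character vector of gene ids.
#' @return A `cell_profiles` object with features in subset order.
#' @export
select_gene_subset <- function(profiles, subset) {
  stopifnot(inherits(profiles, "cell_profiles"))
  present <- subset[subset %in% profiles$feature_names]
  if (length(present) == 0L) stop("gene subset has no overlap with profile features")
  n_missing <- length(subset) - length(present)
  if (n_missing > 0L) message("select_gene_subset: ", n_missing, " subset gene(s) not in profiles; dropped")
  cell_profiles(profiles$values[present, , drop = FALSE], profiles$modality)
}

#' Read a gene-subset file (one gene id per line)
#' @param path Path to a plain-text file.
#' @return Character vector of gene ids.
#' @export
read_gene_subset <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

# ---- model-input normalisation --------------------------------------------
# Per-gene z-score statistics are fit on training cells only and reused for
# validation/test profiles, so no information from held-out cells leaks into
# the inputs. MUT profiles stay binary.

#' Fit per-gene normalisation statistics on training cells
#'
#' @param profiles A `cell_profiles` object restricted to training cells.
#' @return An object of class `omics_normalizer` (per-gene mean and sd).
#' @export
fit_normalizer <- function(profiles) {
  stopifnot(inherits(profiles, "cell_profiles"))
  mu <- rowMeans(profiles$values)
  sd <- apply(profiles$values, 1L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  structure(list(mean = mu, sd = sd, modality = profiles$modality,
                 feature_names = profiles$feature_names),
            class = "omics_normalizer")
}

#' Apply fitted normalisation statistics to profiles
#' @param norm An `omics_normalizer`.
#' @param profiles A `cell_profiles` object with the same features.
#' @return Normalised `cell_profiles`.
#' @export
apply_normalizer <- function(norm, profiles) {
  stopifnot(inherits(norm, "omics_normalizer"), inherits(profiles, "cell_profiles"))
  if (!identical(norm$feature_names, profiles$feature_names)) {
    stop("normalizer feature order does not match profiles")
  }
  if (profiles$modality == "MUT") return(profiles)
  vals <- (profiles$values - norm$mean) / norm$sd
  cell_profiles(vals, profiles$modality)
}
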