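# Response-table construction, cleaning, leakage-controlled splitting, and
# batch loading.

.METRICS <- c("lnIC50", "AUC", "ActArea")
.STRATEGIES <- c("random", "leave_cell_out", "leave_drug_out", "strict")

#' Names of the supported splitting strategies
#' @return Character vector of length 4.
#' @export
split_strategies <- function() .STRATEGIES

#' Names of the supported response metrics
#' @return Character vector of length 3.
#' @export
response_metrics <- function() .METRICS

#' Construct a drug-response dataset handle
#'
#' Joins a response table against cell omics profiles and drug structures.
#' Records whose cell id has no profile in every supplied modality, or whose
#' drug has no parsable SMILES, are excluded with a message.
#'
#' @param responses Path to a CSV with header
#'   `cell_id,drug_id,smiles,response,metric` (`smiles` and `metric`
#'   optional), or an equivalent data frame.
#' @param omics Named list of `cell_profiles` objects (e.g. `EXP`, `MUT`).
#' @param drugs Optional named character vector mapping drug ids to SMILES,
#'   used when the response table has no `smiles` column.
#' @return An object of class `dr_data`: `records` (data frame), `omics`,
#'   `drug_smiles`.
#' @export
build_drdata <- function(responses, omics, drugs = NULL) {
  df <- if (is.character(responses)) utils::read.csv(responses, stringsAsFactors = FALSE) else as.data.frame(responses)
  need <- c("cell_id", "response")
  if (!all(need %in% names(df))) {
    stop("response table missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!("drug_id" %in% names(df)) && !("smiles" %in% names(df))) {
    stop("response table needs a drug identifier column ('drug_id' or 'smiles')")
  }
  if (!("smiles" %in% names(df))) {
    if (is.null(drugs)) stop("no 'smiles' column and no drug id -> SMILES map supplied")
    df$smiles <- unname(drugs[df$drug_id])
  }
  if (!("drug_id" %in% names(df))) df$drug_id <- df$smiles
  if (!("metric" %in% names(df))) df$metric <- "lnIC50"
  bad_metric <- !(df$metric %in% .METRICS)
  if (any(bad_metric)) stop("unknown response metric(s): ", paste(unique(df$metric[bad_metric]), collapse = ", "))

  stopifnot(is.list(omics), length(omics) > 0L)
  for (o in omics) stopifnot(inherits(o, "cell_profiles"))
  known_cells <- Reduce(intersect, lapply(omics, function(o) o$cell_ids))
  drop_cell <- !(df$cell_id %in% known_cells)
  if (any(drop_cell)) {
    message("build_drdata: excluded ", sum(drop_cell), " record(s) with no cell profile")
    df <- df[!drop_cell, , drop = FALSE]
  }
  uniq <- unique(df[, c("drug_id", "smiles")])
  parsable <- vapply(uniq$smiles, function(s) !is.na(s) && is_valid_smiles(s), TRUE)
  if (any(!parsable)) {
    message("build_drdata: excluded ", sum(df$drug_id %in% uniq$drug_id[!parsable]),
            " record(s) for ", sum(!parsable), " drug(s) with unparsable SMILES")
    df <- df[df$drug_id %in% uniq$drug_id[parsable], , drop = FALSE]
  }
  records <- df[, c("cell_id", "drug_id", "smiles", "response", "metric")]
  rownames(records) <- NULL
  structure(list(records = records, omics = omics,
                 drug_smiles = stats::setNames(uniq$smiles[parsable], uniq$drug_id[parsable])),
            class = "dr_data")
}

#' @export
print.dr_data <- function(x, ...) {
  cat("<dr_data> ", nrow(x$records), " records, ",
      length(unique(x$records$cell_id)), " cells, ",
      length(unique(x$records$drug_id)), " drugs; omics: ",
      paste(names(x$omics), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Clean a response record table
#'
#' Drops records with non-finite responses or unparsable SMILES, and
#' collapses duplicate (cell, drug) pairs to their mean response (an
#' order-independent rule). All drops and merges are reported via messages.
#'
#' @param x A `dr_data` handle or a record data frame.
#' @param ... Unused.
#' @return Same class as the input, with cleaned records.
#' @export
clean <- function(x, ...) UseMethod("clean")

#' @rdname clean
#' @export
clean.data.frame <- function(x, ...) {
  n0 <- nrow(x)
  bad_resp <- !is.finite(x$response)
  if (any(bad_resp)) message("clean: dropped ", sum(bad_resp), " record(s) with non-finite response")
  x <- x[!bad_resp, , drop = FALSE]
  uniq <- unique(x$smiles)
  ok <- vapply(uniq, function(s) !is.na(s) && is_valid_smiles(s), TRUE)
  if (any(!ok)) {
    n_bad <- sum(x$smiles %in% uniq[!ok])
    message("clean: dropped ", n_bad, " record(s) with unparsable SMILES")
    x <- x[x$smiles %in% uniq[ok], , drop = FALSE]
  }
  key <- paste(x$cell_id, x$drug_id, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- nrow(x) - length(unique(key))
    agg <- stats::aggregate(response ~ cell_id + drug_id, data = x, FUN = mean)
    meta <- x[!duplicated(key), c("cell_id", "drug_id", "smiles", "metric")]
    x <- merge(meta, agg, by = c("cell_id", "drug_id"), sort = FALSE)
    x <- x[, c("cell_id", "drug_id", "smiles", "response", "metric")]
    message("clean: merged ", n_dup, " duplicate (cell, drug) record(s) by mean response")
  }
  if (nrow(x) == 0L) stop("clean: no records remain after cleaning")
  message("clean: ", n0, " -> ", nrow(x), " records")
  rownames(x) <- NULL
  x
}

#' @rdname clean
#' @export
clean.dr_data <- function(x, ...) {
  x$records <- clean(x$records)
  x
}

# Partition n entities into train/val/test counts: floor(fraction x n) for
# val and test (but at least one entity each, so small drug/cell sets can
# still be split), remainder to train. Deterministic.
.part_sizes <- function(n, fractions) {
  n_val <- max(1L, floor(fractions[2L] * n))
  n_test <- max(1L, floor(fractions[3L] * n))
  n_train <- n - n_val - n_test
  if (n_train < 1L) {
    stop("too few entities to fill all parts: need at least 3, got ", n)
  }
  c(train = n_train, val = n_val, test = n_test)
}

.assign_parts <- function(entities, fractions) {
  n <- length(entities)
  sizes <- .part_sizes(n, fractions)
  perm <- sample(entities)
  list(train = perm[seq_len(sizes[1L])],
       val = perm[sizes[1L] + seq_len(sizes[2L])],
       test = perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])])
}

#' Split response records with leakage control
#'
#' Four strategies: `random` partitions records; `leave_cell_out` and
#' `leave_drug_out` partition cells (respectively drugs) so the three parts
#' share no entity, and records follow their entity; `strict` partitions
#' cells and drugs independently and keeps a record only when its cell and
#' drug fall in the same part, discarding cross-part pairs (the only
#' leakage-safe treatment), so test pairs are novel-cell AND novel-drug.
#'
#' @param records Record data frame (or `dr_data`).
#' @param strategy One of [split_strategies()].
#' @param fractions Numeric triple summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed Integer seed; the split is a pure function of
#'   (records, strategy, fractions, seed).
#' @return An object of class `split_result` with `train`/`val`/`test`
#'   record data frames, `discarded` (strict only), and the split metadata.
#' @export
split_records <- function(records, strategy = split_strategies(),
                          fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (inherits(records, "dr_data")) records <- records$records
  strategy <- match.arg(strategy)
  stopifnot(length(fractions) == 3L, all(fractions > 0), abs(sum(fractions) - 1) < 1e-8)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  discarded <- records[0L, , drop = FALSE]
  if (strategy == "random") {
    sizes <- .part_sizes(nrow(records), fractions)
    perm <- sample(nrow(records))
    parts <- list(train = records[perm[seq_len(sizes[1L])], , drop = FALSE],
                  val = records[perm[sizes[1L] + seq_len(sizes[2L])], , drop = FALSE],
                  test = records[perm[sizes[1L] + sizes[2L] + seq_len(sizes[3L])], , drop = FALSE])
  } else if (strategy %in% c("leave_cell_out", "leave_drug_out")) {
    col <- if (strategy == "leave_cell_out") "cell_id" else "drug_id"
    ent <- .assign_parts(sort(unique(records[[col]])), fractions)
    parts <- lapply(ent, function(e) records[records[[col]] %in% e, , drop = FALSE])
  } else {  # strict
    cell_part <- .assign_parts(sort(unique(records$cell_id)), fractions)
    drug_part <- .assign_parts(sort(unique(records$drug_id)), fractions)
    part_of <- function(x, pp) {
      out <- rep(NA_character_, length(x))
      for (nm in names(pp)) out[x %in% pp[[nm]]] <- nm
      out
    }
    pc <- part_of(records$cell_id, cell_part)
    pd <- part_of(records$drug_id, drug_part)
    keep <- pc == pd
    discarded <- records[!keep, , drop = FALSE]
    message("split_records(strict): discarded ", sum(!keep), " cross-part record(s)")
    parts <- lapply(c(train = "train", val = "val", test = "test"), function(nm) {
      records[keep & pc == nm, , drop = FALSE]
    })
  }
  parts <- lapply(parts, function(d) { rownames(d) <- NULL; d })
  rownames(discarded) <- NULL
  structure(c(parts, list(discarded = discarded, strategy = strategy,
                          fractions = fractions, seed = seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> ", x$strategy, " (seed ", x$seed, "): ",
      nrow(x$train), "/", nrow(x$val), "/", nrow(x$test), " train/val/test",
      if (nrow(x$discarded) > 0L) paste0(", ", nrow(x$discarded), " discarded") else "",
      "\n", sep = "")
  invisible(x)
}

#' Serialize a split to three CSVs plus a JSON manifest
#' @param split A `split_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "val", "test")) {
    utils::write.csv(split[[part]], file.path(dir, paste0(part, ".csv")), row.names = FALSE)
  }
  manifest <- list(strategy = split$strategy, seed = split$seed,
                   fractions = split$fractions,
                   sizes = list(train = nrow(split$train), val = nrow(split$val),
                                test = nrow(split$test), discarded = nrow(split$discarded)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Create a reproducible batch loader
#'
#' @param n_or_records Record count or record data frame.
#' @param batch_size Records per batch (last batch may be smaller).
#' @param shuffle Reshuffle record order every epoch (seeded).
#' @param seed Integer seed for the shuffle stream.
#' @return An object of class `dr_loader`; `$batches(epoch)` returns the
#'   list of record-index vectors for that epoch. Every record appears
#'   exactly once per epoch; a fixed seed reproduces the exact batch order.
#' @export
make_loader <- function(n_or_records, batch_size = 32L, shuffle = TRUE, seed = 1L) {
  n <- if (is.data.frame(n_or_records)) nrow(n_or_records) else as.integer(n_or_records)
  stopifnot(batch_size >= 1L, n >= 1L)
  batches <- function(epoch = 1L) {
    ord <- if (shuffle) {
      old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
      set.seed(seed + 7919L * (epoch - 1L))
      sample(n)
    } else seq_len(n)
    split(ord, ceiling(seq_along(ord) / batch_size))
  }
  structure(list(batches = batches, n = n, batch_size = batch_size,
                 shuffle = shuffle, seed = seed),
            class = "dr_loader")
}

#' Load a public pharmacogenomic screen from pre-placed files
#'
#' Looks for `exp.tsv`, `mut.tsv`, `cnv.tsv` and `responses.csv` under
#' `cache_dir/<name>/` (the same formats the synthetic fixture writer
#' emits) and normalises them to a `dr_data` handle. No download is
#' attempted; files must be placed beforehand.
#'
#' @param name `"CCLE"` or `"GDSC"`.
#' @param cache_dir Directory holding the pre-placed files.
#' @return A `dr_data` handle.
#' @export
load_public_dataset <- function(name = c("CCLE", "GDSC"), cache_dir) {
  name <- match.arg(name)
  root <- file.path(cache_dir, name)
  need <- file.path(root, c("exp.tsv", "responses.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("dataset '", name, "' not found under ", root, ".\n",
         "Expected layout:\n  ", root, "/exp.tsv   (genes x cells TSV)\n  ",
         root, "/mut.tsv   (optional binary TSV)\n  ",
         root, "/cnv.tsv   (optional numeric TSV)\n  ",
         root, "/responses.csv (cell_id,drug_id,smiles,response,metric)\n",
         "Place the files there and retry.")
  }
  omics <- list(EXP = load_omics_matrix(file.path(root, "exp.tsv"), "EXP"))
  if (file.exists(file.path(root, "mut.tsv"))) omics$MUT <- load_omics_matrix(file.path(root, "mut.tsv"), "MUT")
  if (file.exists(file.path(root, "cnv.tsv"))) omics$CNV <- load_omics_matrix(file.path(root, "cnv.tsv"), "CNV")
  build_drdata(file.path(root, "responses.csv"), omics)
}
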