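# Synthetic pharmacogenomic fixture generator. Emulates a small cell-line
# screen — omics matrices, a gene-set collection, and a full cells x drugs
# response grid with a planted, learnable signal — in the exact file formats
# the loaders consume (TSV / GMT / CSV). Ground-truth parameters are
# returned so tests can verify signal recovery.

#' Default toy drug list
#'
#' Eight small valid molecules with stable graph/tokenizer shapes (ethanol,
#' benzene, aspirin, caffeine, chlorobenzene, ibuprofen, toluene, phenol),
#' plus two deliberately invalid strings used to exercise cleaning.
#'
#' @param include_invalid Append the two invalid SMILES (default FALSE).
#' @return Named character vector of SMILES keyed by drug id.
#' @export
toy_drugs <- function(include_invalid = FALSE) {
  d <- c(
    ethanol = "CCO",
    benzene = "c1ccccc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    chlorobenzene = "Clc1ccccc1",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    toluene = "Cc1ccccc1",
    phenol = "Oc1ccccc1"
  )
  if (include_invalid) d <- c(d, bad_one = "not_a_smiles", bad_two = "(((")
  d
}

#' Generate a synthetic drug-response fixture
#'
#' Expression is standard normal per gene, mutation status Bernoulli(`mut_rate`),
#' copy number normal(0, 0.5). The response for cell c and drug d is
#' `w . EXP_subset(c) + offset_d (+ b_d * (w2 . EXP_subset(c)) for the
#' bilinear model) + noise`, a signal that a drug-response model can recover
#' by construction.
#'
#' @param n_cells Number of cell lines (default 20).
#' @param n_genes Number of genes (default 50).
#' @param drugs Named character vector of SMILES (default [toy_drugs()]).
#' @param effect_model `"linear"` or `"bilinear"`.
#' @param noise_sd Standard deviation of additive Gaussian response noise.
#' @param mut_rate Planted per-entry mutation probability (default 0.1).
#' @param n_signal_genes Number of genes carrying response signal (default 5).
#' @param seed RNG seed; fixed seed gives bitwise-identical output.
#' @return A list with `exp`, `mut`, `cnv` (`cell_profiles`), `gene_sets`,
#'   `responses` (data frame `cell_id, drug_id, smiles, response, metric`),
#'   and `truth` (planted parameters).
#' @export
generate_fixture <- function(n_cells = 20L, n_genes = 50L, drugs = toy_drugs(),
                             effect_model = c("linear", "bilinear"),
                             noise_sd = 0.1, mut_rate = 0.1,
                             n_signal_genes = 5L, seed = 1L) {
  effect_model <- match.arg(effect_model)
  stopifnot(n_cells >= 2L, n_genes >= 2L, noise_sd >= 0, n_signal_genes <= n_genes)
  set.seed(seed)
  genes <- sprintf("G%03d", seq_len(n_genes))
  cells <- sprintf("CELL%03d", seq_len(n_cells))
  exp_m <- matrix(stats::rnorm(n_genes * n_cells), n_genes, n_cells, dimnames = list(genes, cells))
  mut_m <- matrix(stats::rbinom(n_genes * n_cells, 1L, mut_rate), n_genes, n_cells, dimnames = list(genes, cells))
  cnv_m <- matrix(stats::rnorm(n_genes * n_cells, 0, 0.5), n_genes, n_cells, dimnames = list(genes, cells))

  sig_genes <- genes[seq_len(n_signal_genes)]
  w <- stats::rnorm(n_signal_genes)
  offsets <- stats::rnorm(length(drugs))
  names(offsets) <- names(drugs)
  lin <- drop(crossprod(exp_m[sig_genes, , drop = FALSE], w))
  bilin_w <- stats::rnorm(n_signal_genes, sd = 0.5)
  bilin_b <- if (effect_model == "bilinear") stats::rnorm(length(drugs), sd = 0.5) else rep(0, length(drugs))
  names(bilin_b) <- names(drugs)
  bil <- drop(crossprod(exp_m[sig_genes, , drop = FALSE], bilin_w))

  grid <- expand.grid(cell_id = cells, drug_id = names(drugs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  signal <- lin[grid$cell_id] + offsets[grid$drug_id] +
    bilin_b[grid$drug_id] * bil[grid$cell_id]
  responses <- data.frame(
    cell_id = grid$cell_id,
    drug_id = grid$drug_id,
    smiles = unname(drugs[grid$drug_id]),
    response = unname(signal + stats::rnorm(nrow(grid), sd = noise_sd)),
    metric = "lnIC50",
    stringsAsFactors = FALSE
  )

  n_sets <- max(30L, n_genes %/% 10L)
  gene_sets <- lapply(seq_len(n_sets), function(i) {
    size <- min(n_genes, 5L + (i %% 6L))
    sample(genes, size)
  })
  names(gene_sets) <- sprintf("PATHWAY_%02d", seq_len(n_sets))
  gene_sets[[1L]] <- sig_genes  # one pathway carries the signal genes

  list(
    exp = cell_profiles(exp_m, "EXP"),
    mut = cell_profiles(mut_m, "MUT"),
    cnv = cell_profiles(cnv_m, "CNV"),
    gene_sets = structure(gene_sets, class = "gene_set_collection"),
    responses = responses,
    truth = list(w = stats::setNames(w, sig_genes), offsets = offsets,
                 bilinear_b = bilin_b, bilinear_w = stats::setNames(bilin_w, sig_genes),
                 signal_genes = sig_genes, noise_sd = noise_sd,
                 mut_rate = mut_rate, effect_model = effect_model, seed = seed)
  )
}

#' Write a fixture to disk in loader formats
#'
#' Emits `exp.tsv`, `mut.tsv`, `cnv.tsv` (genes x cells TSV), `pathways.gmt`,
#' `subset.txt` (the signal genes), and `responses.csv`.
#'
#' @param fx A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(prof, name) {
    df <- data.frame(gene_id = prof$feature_names, prof$values, check.names = FALSE)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(fx$exp, "exp.tsv"); wtsv(fx$mut, "mut.tsv"); wtsv(fx$cnv, "cnv.tsv")
  gmt <- vapply(names(fx$gene_sets), function(nm) {
    paste(c(nm, "synthetic", fx$gene_sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(gmt, file.path(dir, "pathways.gmt"))
  writeLines(fx$truth$signal_genes, file.path(dir, "subset.txt"))
  utils::write.csv(fx$responses, file.path(dir, "responses.csv"), row.names = FALSE)
  invisible(dir)
}
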