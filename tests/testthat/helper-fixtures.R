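# Shared test helpers: small hyperparameter sets and a cached fixture so
# featurization work is not repeated across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

small_hp <- function(...) {
  base <- list(d = 16L, embed_dim = 8L, fp_hidden = 32L, dnn_hidden = 32L,
               head_hidden = 16L, rnn_hidden = 8L, dae_hidden = 32L,
               cell_cnn_channels = 4L, heads = 4L)
  do.call(default_hyperparams, utils::modifyList(base, list(...)))
}

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    .fx_cache$fx <- generate_fixture(seed = 1L)
    .fx_cache$omics <- list(
      EXP = .fx_cache$fx$exp, MUT = .fx_cache$fx$mut, CNV = .fx_cache$fx$cnv,
      PES = compute_pathway_scores(.fx_cache$fx$exp, .fx_cache$fx$gene_sets)
    )
  }
  list(fx = .fx_cache$fx, omics = .fx_cache$omics)
}

# Randomized alternative spellings (generated once with an independent
# cheminformatics toolkit and frozen) used to test spelling invariance.
respellings <- list(
  aspirin = c(
    "CC(=O)Oc1ccccc1C(=O)O",
    "CC(=O)Oc1c(C(O)=O)cccc1", "CC(=O)Oc1c(cccc1)C(O)=O", "CC(Oc1ccccc1C(=O)O)=O",
    "O(c1ccccc1C(=O)O)C(C)=O", "O(c1ccccc1C(O)=O)C(=O)C", "OC(=O)c1c(OC(=O)C)cccc1",
    "OC(c1c(cccc1)OC(=O)C)=O", "c1c(C(O)=O)c(OC(C)=O)ccc1", "c1c(OC(C)=O)c(C(O)=O)ccc1",
    "c1cc(C(=O)O)c(OC(=O)C)cc1", "c1ccc(C(=O)O)c(c1)OC(C)=O", "c1ccc(c(OC(C)=O)c1)C(O)=O"
  ),
  ibuprofen = c(
    "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    "C(C(C)C)c1ccc(cc1)C(C)C(=O)O", "C(C)(C(O)=O)c1ccc(cc1)CC(C)C",
    "C(C)(C)Cc1ccc(C(C)C(O)=O)cc1", "C(C)(c1ccc(cc1)CC(C)C)C(O)=O",
    "CC(Cc1ccc(C(C(O)=O)C)cc1)C", "CC(Cc1ccc(C(C)C(=O)O)cc1)C",
    "CC(c1ccc(CC(C)C)cc1)C(=O)O", "CC(c1ccc(cc1)CC(C)C)C(O)=O",
    "O=C(C(C)c1ccc(cc1)CC(C)C)O", "O=C(O)C(C)c1ccc(cc1)CC(C)C",
    "c1(ccc(cc1)C(C)C(O)=O)CC(C)C", "c1c(C(C(=O)O)C)ccc(c1)CC(C)C"
  )
)
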