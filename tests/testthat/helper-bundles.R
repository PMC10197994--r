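# Shared synthetic bundles, generated once per test run.

.bundle_cache <- new.env(parent = emptyenv())

# The default study-condition bundle (full size).
default_bundle <- function() {
  if (is.null(.bundle_cache$default)) {
    .bundle_cache$default <- generate_survey_inputs(generator_config(seed = 101))
  }
  .bundle_cache$default
}

# A reduced bundle for structural tests that do not measure recovery rates.
small_config <- function(seed = 42) {
  generator_config(
    seed = seed, n_family_members = 24, n_decoys = 10,
    groups = c(I = 8, II = 7, III = 6, IV = 3),
    tandem_clusters = list(list(chromosome = "Tr5O", size = 2),
                           list(chromosome = "Tr1P", size = 2)),
    segmental_pairs = 2, n_upregulated_30M = 6, n_silent = 2,
    network_edges = 60
  )
}

small_bundle <- function() {
  if (is.null(.bundle_cache$small)) {
    .bundle_cache$small <- generate_survey_inputs(small_config())
  }
  .bundle_cache$small
}

manifest_members <- function(bundle) {
  g <- bundle$manifest$genes
  g$gene_id[g$role == "member"]
}
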