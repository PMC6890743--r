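# shared fixtures, built once per test run and memoized

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# noiseless 5 coding / 5 lncRNA / 5 decoy fixture with known fates
fixture_cascade <- function() {
  cached("cascade", function() {
    simulate_dataset(simulation_config(
      seed = 2, n_coding = 5, n_lncrna = 5, n_decoy = 5,
      n_hairpins = 0, n_hairpin_decoys = 0, n_etm_sites = 0,
      n_target_sites = 0, n_de = 0, n_corr_pairs = 0, noise_sd = 0))
  })
}

# larger labelled set used to train hexamer tables and for composition stats
fixture_training <- function() {
  cached("training", function() {
    simulate_dataset(simulation_config(
      seed = 77, n_coding = 30, n_lncrna = 30, n_decoy = 0,
      n_hairpins = 0, n_hairpin_decoys = 0, n_etm_sites = 0,
      n_target_sites = 0, n_de = 0, n_corr_pairs = 0))
  })
}

fixture_hexamer_tables <- function() {
  cached("hexamers", function() {
    sim <- fixture_training()
    lab <- sim$truth$labels
    train_hexamer_tables(sim$sequences[lab$id[lab$label == "coding"]],
                         sim$sequences[lab$id[lab$label == "lncrna"]])
  })
}

# miRNA fixture: planted precursors among shuffled decoys
fixture_mir <- function() {
  cached("mir", function() {
    simulate_dataset(simulation_config(
      seed = 11, n_coding = 0, n_lncrna = 0, n_decoy = 0,
      n_hairpins = 10, n_hairpin_decoys = 30, n_etm_sites = 0,
      n_target_sites = 0, n_de = 0, n_corr_pairs = 0))
  })
}

random_rna_str <- function(n, bases = c("A", "C", "G", "U")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

sort_sites <- function(x) {
  x <- x[order(x$site_start, x$bulge_len, x$bulge_pos), ]
  rownames(x) <- NULL
  x
}
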