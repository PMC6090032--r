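# Shared fixtures. The default unit and its calibrated retention model are
# deterministic, so they are built once per test run.
default_unit <- rdna_unit()
default_retention <- retention_model(default_unit)

# genome with only active + hypermethylated copies (closed-form regime)
hyper_genome <- function(cn, f) genome_rdna(cn, f_hyper = f)

# quick NE-vs-membrane pipeline: render one membrane of `ids` with true
# copy numbers `cns`, quantify, return estimates data frame
pipeline_membrane <- function(cns, noise = noise_preset(), seed = 1,
                              n_replicates = 6) {
  ids <- sprintf("S%03d", seq_along(cns))
  lay <- membrane_layout(ids, n_replicates = n_replicates)
  sig <- stats::setNames(10 * cns, ids)
  img <- render_membrane(lay, sig, noise, rng_seed = seed,
                         standard_signal_per_copy_ng = 10)
  quantify_membrane(img)
}
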