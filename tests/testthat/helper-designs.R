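# Shared builders for reduced-scale synthetic datasets used across tests.
# The reduced plate-reader design keeps the structure of the standard one
# (zero-protein baseline, limiting- and excess-protein traces) at a
# fraction of the points.

default_fp_map <- function() observable_map(60, 220, "PS")

reduced_m1_template <- function(noise_sd = NULL) {
  design_template("platereader_std",
                  protein_concs = c(0, 10e-9, 100e-9, 400e-9),
                  grid = seq(0, 1800, by = 60),
                  noise_sd = noise_sd)
}

reduced_m1_set <- function(k_app = 1.51e5, noise_sd = NULL, seed = 1L,
                           true_substrate_conc = NULL) {
  generate_traces(reduced_m1_template(noise_sd), model1_params(k_app),
                  default_fp_map(), seed = seed,
                  true_substrate_conc = true_substrate_conc)
}

sf_map <- function() observable_map(0.05, 0.19, c("PSstar", "PS"))

reduced_m2_template <- function(noise_sd = NULL, replicates = 3L) {
  design_template("stoppedflow",
                  protein_concs = c(0, 0.25e-6, 0.8e-6, 3.13e-6),
                  grid = seq(0, 2, by = 0.004),
                  replicates = replicates, noise_sd = noise_sd)
}

# crude max relative deviation against a reference curve, normalized by
# the reference's largest magnitude (PS(0) = 0 forbids pointwise ratios)
max_rel_dev <- function(x, ref) max(abs(x - ref)) / max(abs(ref))
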