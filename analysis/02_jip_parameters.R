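#!/usr/bin/env Rscript
# Derive the full JIP-test parameter set (phi_Po, psi_o, V_J, M0, Area,
# energy fluxes per cross-section, PI_ABS) for every transient.
# Reads results/transients.tsv; writes results/parameters.tsv.

suppressPackageStartupMessages(library(ojipcap))

transients <- read_transients("results/transients.tsv", layout = "long")
res <- analyze_transients(transients)
write_table(res$parameters, "results/parameters.tsv")
if (nrow(res$rejects)) {
  write_table(res$rejects, "results/rejects.tsv")
  cat(sprintf("NOTE: %d degenerate/rejected sample(s), see results/rejects.tsv\n",
              nrow(res$rejects)))
}

cat(sprintf("analyzed %d samples; phi_Po range %.3f-%.3f, PI_ABS range %.2f-%.2f\n",
            nrow(res$parameters),
            min(res$parameters$phi_po), max(res$parameters$phi_po),
            min(res$parameters$pi_abs), max(res$parameters$pi_abs)))
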