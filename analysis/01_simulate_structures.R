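#!/usr/bin/env Rscript
# Build the synthetic study systems: two-domain helical bundles in the
# four canonical gate states, a cytoplasmic-closing transition
# ensemble, a soft-ratchet sampled trajectory and cavity waters.
# Everything downstream (02-06) reads these fixtures from results/.

suppressPackageStartupMessages(library(gatescape))
outdir <- "results/01_structures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 2026

states <- list(occluded = c(0, 0), cyt_open = c(1, 0),
               peri_open = c(0, 1), leak = c(1, 1))
for (nm in names(states)) {
  b <- make_bundle(bundle_spec(gate_cyt = states[[nm]][1],
                               gate_peri = states[[nm]][2], seed = seed))
  write_structure(b, file.path(outdir, paste0(nm, ".pdb")))
}
message("wrote four gate-state bundles (occluded / cyt_open / peri_open / leak)")

# cytoplasmic closure: open -> occluded, 40 frames with 0.15 A noise
start <- make_bundle(bundle_spec(gate_cyt = 1, seed = seed))
end <- make_bundle(bundle_spec(gate_cyt = 0, seed = seed))
closure <- make_transition(start, end, 40, noise_sigma = 0.15,
                           seed = seed)
write_ensemble(closure, file.path(outdir, "closure_transition.pdb"))
message("wrote 40-frame cytoplasmic-closure transition ensemble")

# soft-ratchet run toward the occluded target: the biased sampler that
# stands in for directed transition sampling, at the soft (1e-4 A)
# ratchet scale
ca <- select_atoms(start, names = "CA")
ratchet <- soft_ratchet_sample(start, end,
                               soft_ratchet_config(delta_phi = 1e-4,
                                                   step_sigma = 0.03,
                                                   max_steps = 400,
                                                   seed = seed),
                               progress_atoms = ca)
phi <- attr(ratchet, "phi")
write.table(data.frame(accepted_frame = seq_along(phi), phi = phi),
            file.path(outdir, "ratchet_progress.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("soft ratchet: %d accepted frames, phi %.2f -> %.2f A",
                n_frames(ratchet), phi[1], tail(phi, 1)))

# cavity waters for the occluded bundle at bulk density
occ <- make_bundle(bundle_spec(seed = seed))
waters <- fill_cavity_waters(occ,
                             list(min = c(-8, -8, -19),
                                  max = c(8, 8, 19)),
                             spc_bulk_number_density(), seed = seed,
                             n_frames = 40)
counts <- vapply(waters, nrow, integer(1))
write.table(data.frame(frame = seq_along(counts), n_waters = counts),
            file.path(outdir, "water_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message(sprintf("cavity waters: %.0f +/- %.0f per frame over %d frames",
                mean(counts), sd(counts), length(counts)))
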