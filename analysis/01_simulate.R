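#!/usr/bin/env Rscript
# Generate every synthetic input used by the downstream analyses: the
# three-component bilayer with UndP, the UndP conformer trajectories, the
# two-state mobile-loop protein (simulation trajectory + crystal octamer),
# the Gaussian-blob density map, and the scheduled binding trajectory.
# Each dataset is written in a standard format next to its ground-truth
# manifest so any step can be re-run from disk.

suppressPackageStartupMessages(library(mdmembr))
seed <- 20260928L %% 100000L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mem <- gen_membrane(seed = seed, n_frames = 5)
write_trajectory(mem$trajectory, file.path(out, "membrane.pdb"))
write_manifest(mem$manifest, file.path(out, "membrane_manifest.json"))
cat(sprintf("membrane: %d lipids + %d UndP, %d frames, planted P2 = %.4f\n",
            mem$manifest$n_lipids, mem$manifest$n_undp,
            mem$manifest$n_frames, mem$manifest$planted_p2))

for (mode in c("extended", "coiled", "mixture")) {
  u <- gen_undp_conformers(seed = seed + 1, n_frames = 50, mode = mode)
  write_trajectory(u$trajectory, file.path(out, paste0("undp_", mode, ".xyz")))
  write_manifest(u$manifest, file.path(out, paste0("undp_", mode, "_manifest.json")))
}
cat("UndP conformers: extended / coiled / mixture, 50 frames each\n")

pr <- gen_protein_two_state(seed = seed + 2, n_frames = 200)
write_trajectory(pr$trajectory, file.path(out, "protein_sim.pdb"))
write_trajectory(new_trajectory(pr$crystal$topology, list(pr$crystal$frame)),
                 file.path(out, "protein_crystal_octamer.pdb"))
write_manifest(pr$manifest[setdiff(names(pr$manifest), "mode")],
               file.path(out, "protein_manifest.json"))
cat(sprintf("protein: %d-frame trajectory + %d-chain crystal, loop %d-%d\n",
            pr$manifest$n_frames, pr$manifest$n_chains,
            pr$manifest$loop[1], pr$manifest$loop[2]))

blobs <- data.frame(x = c(8, 17, 25), y = c(10, 10, 25), z = c(12, 12, 25),
                    amplitude = c(6, 4, 5), width = c(0.6, 0.6, 0.7))
dm <- gen_density_map(seed = seed + 3, dims = c(64, 64, 64), spacing = 0.5,
                      blobs = blobs, noise_sd = 0.05)
write_ccp4(dm$grid, file.path(out, "difference_map.ccp4"))
write_manifest(dm$manifest, file.path(out, "map_manifest.json"))
cat(sprintf("density map: 64^3 voxels at 0.5 A, %d blobs (integrals %s)\n",
            nrow(blobs), paste(signif(dm$manifest$blob_integrals, 4),
                               collapse = ", ")))

bind <- gen_binding_trajectory(seed = seed + 4, n_frames = 100)
write_trajectory(bind$trajectory, file.path(out, "binding.pdb"))
write_manifest(bind$manifest, file.path(out, "binding_manifest.json"))
cat("binding trajectory: 100 frames, scheduled contacts at residues",
    paste(names(bind$manifest$schedule), collapse = ", "), "\n")
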