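#!/usr/bin/env Rscript
# Simulate the synthetic peri-ictal EEG study and write it to disk as EDF +
# ground-truth sidecars: a four-seizure series from one "patient" with a
# planted monotone network degradation, plus a single pre/post pair with a
# planted delta-power increase, complexity decrease and edge shifts.
#
# Usage: Rscript analysis/01_simulate.R [--seed N] [--out DIR]

suppressMessages(library(seiznet))
args <- commandArgs(trailingOnly = TRUE)
arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) default else args[i + 1]
}
seed <- as.integer(arg("--seed", "1"))
out <- arg("--out", "results/data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Study conditions: 16-channel 10-20 montage, 256 Hz, 10-min segments.
# Coupling: two-neighbour ring in the delta band (adjacent 0.09, next 0.03);
# degradation removes 9.5% of the planted coupling per segment step.
ring <- matrix(0, 16, 16)
for (i in 1:16) for (d in 1:2) {
  j <- ((i + d - 1) %% 16) + 1
  ring[i, j] <- ring[j, i] <- c(0.09, 0.03)[d]
}

series_cfg <- synth_config(
  duration = 120,            # scaled-down segments keep this script quick;
                             # the generator itself defaults to 600 s
  coupling = list(delta = ring),
  effect = pre_post_effect(edge_shifts = list(delta = -0.095 * ring),
                           seizure_trend = 1),
  seed = seed)
series <- generate_seizure_series(series_cfg, n_seizures = 4)
for (lb in names(series)) {
  write_edf(series[[lb]], file.path(out, sprintf("series_%s.edf", lb)),
            extra = list(study = "seizure_series", segment = lb,
                         coupling_delta = ring,
                         edge_shift_scale = -0.095, seizure_trend = 1))
}
message(sprintf("wrote %d series segments (4 seizures) to %s", length(series), out))

# Pre/post contrasts, split factorially: pair A plants the channel-level
# effects (delta power + complexity) plus artifacts; pair B plants the
# coupling edge shifts. Kept separate because a complexity shift reshapes
# in-band spectra and hence coherence on its own channels, which would
# contaminate edge-recovery counts.
planted_channels <- c(1, 4, 7, 10, 13, 16)
ratio <- rep(1, 16); ratio[planted_channels] <- 2
shift <- rep(0, 16); shift[planted_channels] <- -0.9

pairA_cfg <- synth_config(
  duration = 600,
  effect = pre_post_effect(delta_power_ratio = ratio, entropy_shift = shift),
  artifact_rate = 0.1,
  seed = seed + 1)
for (state in c("pre", "post")) {
  rec <- generate_recording(pairA_cfg, state, 1)
  art <- inject_artifacts(rec, rate = pairA_cfg$artifact_rate, amplitude = 150,
                          seed = seed + 2 + (state == "post"))
  write_edf(art$recording, file.path(out, sprintf("pair_1-%s.edf", state)),
            extra = list(study = "channel_effects_pair",
                         segment = sprintf("1-%s", state),
                         planted_channels = planted_channels,
                         delta_power_ratio = 2, entropy_shift = -0.9,
                         planted_artifact_windows = art$windows))
  message(sprintf("wrote pair_1-%s.edf with %d planted artifact windows",
                  state, length(art$windows)))
}

wk <- rbind(c(1, 2), c(3, 4), c(5, 6))     # weakened pairs
en <- rbind(c(7, 8), c(9, 10), c(11, 12))  # enhanced pairs
K <- matrix(0, 16, 16); E <- matrix(0, 16, 16)
K[wk] <- 0.40; K[wk[, 2:1]] <- 0.40; E[wk] <- -0.25; E[wk[, 2:1]] <- -0.25
K[en] <- 0.10; K[en[, 2:1]] <- 0.10; E[en] <- 0.25; E[en[, 2:1]] <- 0.25

pairB_cfg <- synth_config(
  duration = 600,
  coupling = list(delta = K),
  effect = pre_post_effect(edge_shifts = list(delta = E)),
  seed = seed + 10)
for (state in c("pre", "post")) {
  rec <- generate_recording(pairB_cfg, state, 1)
  write_edf(rec, file.path(out, sprintf("edgepair_1-%s.edf", state)),
            extra = list(study = "edge_effects_pair",
                         segment = sprintf("1-%s", state),
                         weakened_pairs = wk, enhanced_pairs = en,
                         edge_shift = 0.25))
  message(sprintf("wrote edgepair_1-%s.edf", state))
}
message("done")
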