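#!/usr/bin/env Rscript

# Build the five-block stimulus session: the patterned scale sequence, its
# matched random permutation, and the two-note oddball stream; write the
# event tables, a demo audio rendering, and the envelope spectrum of the
# patterned block.
#
# Outputs under results/stimuli/.

suppressMessages(library(noteERP))

seed <- 20260101L
out_dir <- "results/stimuli"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config("full")$stimulus

message("Building the five 5-min blocks (", cfg$rate_hz, " Hz) ...")
pattern <- build_pattern_block(cfg$start_key_pc, default_shapes(),
                               cfg$block_s, cfg$rate_hz, cfg$start_anchor)
random <- build_random_block(pattern, seed_stream(seed, "random-order"))
oddball <- build_oddball_block(cfg$standard_midi, cfg$deviant_midi,
                               cfg$p_deviant, nrow(pattern$events),
                               seed_stream(seed, "oddball-order"))

# blocks 1/2 and 3/4 repeat the same sequences (yoked design)
blocks <- list(block1 = pattern, block2 = pattern, block3 = random,
               block4 = random, block5 = oddball)
for (nm in names(blocks)) {
  write_events(blocks[[nm]], file.path(out_dir, paste0(nm, "_events.tsv")),
               fs = 500)
}
message("Opening of block 1: ",
        paste(pattern$events$name[1:9], collapse = " "),
        "  (the sliding three-note window)")
message("Block 5: ", sum(oddball$events$code == "deviant"), " deviants / ",
        sum(oddball$events$code == "standard"), " standards")

# Latin-square block orders for the 13 subjects
orders <- t(vapply(0:12, latin_square_order, integer(5),
                   n_blocks = 5, seed = seed_stream(seed, "order")))
write.table(data.frame(subject = 1:13, orders), sep = "\t",
            file = file.path(out_dir, "block_orders.tsv"),
            quote = FALSE, row.names = FALSE,
            col.names = c("subject", paste0("slot", 1:5)))

message("Rendering a 30 s audio excerpt of block 1 (44.1 kHz WAV) ...")
excerpt <- build_pattern_block(cfg$start_key_pc, default_shapes(), 30,
                               cfg$rate_hz, cfg$start_anchor)
write_wav(render_sequence(excerpt, cfg$fs_audio), fs = cfg$fs_audio,
          path = file.path(out_dir, "block1_excerpt.wav"))

message("Envelope spectrum of the full patterned block ...")
audio <- render_sequence(pattern, cfg$fs_audio)
spec <- envelope_spectrum(audio, cfg$fs_audio)
keep <- spec$freq <= 30
write.table(round(spec[keep, ], 8), file.path(out_dir, "envelope_spectrum.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("Envelope power peaks at ", round(envelope_peak(spec), 4),
        " Hz (the note presentation rate); harmonics follow at 8 and 12 Hz.")
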