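# Default MYB repeat profile configuration. The weight matrices are built at
# load time from the bundled synthetic seed alignment. The score threshold
# was calibrated on synthetic positives/negatives to keep the per-protein
# false-positive rate at or below 1%: over 2000 random 300-aa proteins the
# best anchor-matching window scored -62 or lower, while planted repeats
# scored 83 or higher; 25 sits between the two distributions with a wide
# margin on both sides (see the methods vignette).
version: 1
seed_alignment: myb_seed_alignment_synthetic.faa
score_threshold: 25.0
max_linker: 40
repeats:
  R2:
    length: 53
    anchors: [6, 27, 48]
    anchor_residues: ["W", "W", "W"]
    spacings:
      - {min: 20, max: 21, skip_column: 17}
      - {min: 20, max: 21, skip_column: 38}
  R3:
    length: 52
    anchors: [6, 25, 44]
    anchor_residues: ["FW", "W", "W"]
    spacings:
      - {min: 19, max: 19}
      - {min: 19, max: 19}
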