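Full-genome model configurations
================================

These configs encode the package's two ready-built models at reference-genome
scale.  They are templates: reference sequences are never downloaded or
bundled, so replace the `genome:` path with your local FASTA before running.

- sir_sacCer3_config.yaml : SIR telomeric-silencing model, variant 2
  (gapped double-motif seeding).  Point `genome:` at a SacCer3 FASTA.
  The full-scale study design runs 200 cycles, snapshots every 10, and
  aggregates 100 replicates, e.g.:
    layersim-cli simulate --config sir_sacCer3_config.yaml \
        --out runs/ --replicates 100 --base-seed 1
  Abundances (500/factor) are package defaults with no literature value
  behind them; treat them as a starting point.

- oskm_hg38_config.yaml : OSKM activators vs CpG-island repressor with
  activator statewidth 10000 bp.  Point `genome:` at an hg38 FASTA.  TSS
  summaries additionally need a 1-bp TSS BED (e.g. derived from the MANE
  select transcript set, one TSS per gene) passed to `summarize tss`.
  Sweep `statewidth` by editing the four activator entries (the full-scale
  sweep spans 200-50000 bp); abundances are the model's standard values.

Both configs are also reproducible in R via write_sim_config(build_sir_model(2), ...)
and write_sim_config(build_oskm_model(...), ...).
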