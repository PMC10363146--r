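# Bundled two-cohort synthetic run: shared 4-gene cross-cohort core
# (genes 1-4) inside variant-specific all-stage cores. Sized for a quick
# end-to-end demonstration; enlarge n_genes / samples_per_group for the
# reference simulation (2000 genes, 100 samples per group).
hub: "MYC|4609"
rs_min: 0.3
p_max: 0.05
alpha: 0.05
seed: 1
cohorts:
  SYNTH1:
    synth:
      variant: A
      n_genes: 600
      samples_per_group: {"N": 40, S1: 40, S2: 40, S3: 40, S4: 40}
  SYNTH2:
    synth:
      variant: B
      n_genes: 600
      samples_per_group: {"N": 40, S1: 40, S2: 40, S3: 40, S4: 40}
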