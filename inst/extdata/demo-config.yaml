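# Demo pipeline run: simulate a 4-population dataset with a gamma = 0.2
# P3 -> P2 admixture pulse, filter it at the min4 tier, extract SNPs and
# run one pooled-frequency D test.
seed: 42
stages: [simulate, filter, snps, dstat]
simulate:
  preset: dstat
  gamma: 0.2
  n_loci: 300
filter:
  tier: min4
dstat:
  n_boot: 1000
  z_threshold: 3.5
  tests:
    - p1: P1
      p2: P2
      p3: P3
      p4: O
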