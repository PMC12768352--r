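synthetic_ct_fig1d_like.tsv
  SYNTHETIC qPCR Ct table (not measured data). Three biological replicates
  of a knockdown experiment (group eGFP_dsRNA) against a scrambled-trigger
  control (group srGFP), target gene eGFP, reference gene HKG4, constructed
  so that the comparative-Ct analysis yields roughly 40% knockdown. Used by
  examples and the acceptance script as a worked 2^-ddCt input.
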