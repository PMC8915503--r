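{
  "n-samples": 300,
  "n-variants": 2000,
  "n-genes": 200,
  "seed": 1,
  "fdr": 0.05,
  "window": 100000
}
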