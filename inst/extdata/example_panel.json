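{
  "assays": [
    {
      "assay_id": "MUT-CYSLTR2",
      "kind": "mutation_duplex",
      "locus_id": "CYSLTR2",
      "ch1_allele": "mut",
      "ch2_allele": "wt",
      "reference_assay_id": null
    },
    {
      "assay_id": "CN-CYSLTR2",
      "kind": "cn_multiplex",
      "locus_id": "CYSLTR2",
      "ch1_allele": "total",
      "ch2_allele": "reference",
      "reference_assay_id": null
    }
  ]
}
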