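{
  "loci": [
    {
      "locus_id": "CYSLTR2",
      "germline_copies": 2,
      "alleles": [
        "mut",
        "wt"
      ]
    }
  ],
  "populations": [
    {
      "id": "healthy",
      "parent": null,
      "copies": {
        "CYSLTR2": {
          "mut": 0,
          "wt": 2
        }
      }
    },
    {
      "id": "cloneI",
      "parent": "healthy",
      "copies": {
        "CYSLTR2": {
          "mut": 1,
          "wt": 1
        }
      }
    },
    {
      "id": "cloneII",
      "parent": "cloneI",
      "copies": {
        "CYSLTR2": {
          "mut": 1,
          "wt": 0
        }
      }
    }
  ]
}
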