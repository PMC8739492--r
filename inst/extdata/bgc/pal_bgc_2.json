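{
  "bgc_id": "pal_BGC_2",
  "starter_monomer": "3-methylcrotonic_acid",
  "genes": [
    {
      "gene_id": "palA2",
      "trans_acting": false,
      "domains": [
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "LLM"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "DH"
        },
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "DH"
        },
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "DH"
        },
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "C_trunc"
        }
      ]
    },
    {
      "gene_id": "palE",
      "trans_acting": true,
      "domains": [
        {
          "kind": "AT",
          "label": "malonate_specific"
        }
      ]
    },
    {
      "gene_id": "palF",
      "trans_acting": true,
      "domains": [
        {
          "kind": "AT",
          "label": "relaxed_specificity"
        }
      ]
    },
    {
      "gene_id": "palK",
      "trans_acting": true,
      "domains": [
        {
          "kind": "ACP"
        }
      ]
    },
    {
      "gene_id": "palL",
      "trans_acting": true,
      "domains": [
        {
          "kind": "HCS"
        }
      ]
    },
    {
      "gene_id": "palM",
      "trans_acting": true,
      "domains": [
        {
          "kind": "KS"
        }
      ]
    },
    {
      "gene_id": "palN",
      "trans_acting": true,
      "domains": [
        {
          "kind": "ECH"
        }
      ]
    },
    {
      "gene_id": "palO",
      "trans_acting": true,
      "domains": [
        {
          "kind": "ECH"
        }
      ]
    },
    {
      "gene_id": "palP",
      "trans_acting": true,
      "domains": [
        {
          "kind": "GTF"
        }
      ]
    },
    {
      "gene_id": "palQ",
      "trans_acting": true,
      "domains": [
        {
          "kind": "CT"
        }
      ]
    }
  ],
  "site_annotations": [
    {
      "module": 5,
      "type": "trans_ER"
    }
  ],
  "tailoring": [
    {
      "enzyme": "CT",
      "target": "default"
    }
  ]
}
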