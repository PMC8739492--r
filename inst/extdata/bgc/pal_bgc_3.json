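{
  "bgc_id": "pal_BGC_3",
  "starter_monomer": "3-methylcrotonic_acid",
  "genes": [
    {
      "gene_id": "palA",
      "trans_acting": false,
      "domains": [
        {
          "kind": "ACP"
        },
        {
          "kind": "ACP_beta"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "PCP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "cMT"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "C"
        },
        {
          "kind": "A",
          "substrate": "glycine"
        }
      ]
    },
    {
      "gene_id": "palB",
      "trans_acting": false,
      "domains": [
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "DH",
          "shift": true
        },
        {
          "kind": "cMT"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "DH",
          "shift": true
        }
      ]
    },
    {
      "gene_id": "palC",
      "trans_acting": false,
      "domains": [
        {
          "kind": "KR",
          "kr_type": "B"
        },
        {
          "kind": "cMT"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "KR",
          "kr_type": "A"
        },
        {
          "kind": "DHt"
        },
        {
          "kind": "ACP"
        },
        {
          "kind": "KS"
        },
        {
          "kind": "ECH"
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
        }
      ]
    },
    {
      "gene_id": "palD",
      "trans_acting": false,
      "domains": [
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
      "gene_id": "palG",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "polysacc_synt_2"
        }
      ]
    },
    {
      "gene_id": "palH",
      "trans_acting": true,
      "domains": [
        {
          "kind": "LO"
        }
      ]
    },
    {
      "gene_id": "palI",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "ABC_transporter"
        }
      ]
    },
    {
      "gene_id": "palJ",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "band7"
        }
      ]
    },
    {
      "gene_id": "ppt1",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "PPTase"
        }
      ]
    },
    {
      "gene_id": "nmo1",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "nitronate_monooxygenase"
        }
      ]
    },
    {
      "gene_id": "hyp1",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
        }
      ]
    },
    {
      "gene_id": "hyp2",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
        }
      ]
    },
    {
      "gene_id": "hyp3",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
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
    },
    {
      "gene_id": "hyp4",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
        }
      ]
    },
    {
      "gene_id": "hyp5",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
        }
      ]
    },
    {
      "gene_id": "hyp6",
      "trans_acting": true,
      "domains": [
        {
          "kind": "OTHER",
          "label": "hypothetical"
        }
      ]
    }
  ],
  "site_annotations": [
    {
      "module": 7,
      "type": "hcs_site"
    },
    {
      "module": 9,
      "type": "trans_ER"
    },
    {
      "module": 13,
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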