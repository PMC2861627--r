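{
  "comment": "Expression-profile acceptance criteria per genotype. 'order' lists the genes expected to be expressed in successive (offset-ordered) windows; 'clamped_on' is a gene held ON for the whole simulation (overexpression); 'absent' genes must never be expressed; 'persist' requires the last gene of 'order' to remain expressed through the final step.",
  "criteria": [
    {"genotype": "wt",    "order": ["hb", "Kr", "pdm", "cas"], "clamped_on": null,  "absent": [],            "persist": false},
    {"genotype": "hb-",   "order": ["Kr", "pdm", "cas"],       "clamped_on": null,  "absent": ["hb"],        "persist": false},
    {"genotype": "Kr-",   "order": ["hb", "pdm", "cas"],       "clamped_on": null,  "absent": ["Kr"],        "persist": false},
    {"genotype": "pdm-",  "order": ["hb", "Kr", "cas"],        "clamped_on": null,  "absent": ["pdm"],       "persist": true},
    {"genotype": "cas-",  "order": ["hb", "Kr", "pdm"],        "clamped_on": null,  "absent": ["cas"],       "persist": true},
    {"genotype": "hb++",  "order": ["Kr"],                     "clamped_on": "hb",  "absent": ["pdm", "cas"],"persist": true},
    {"genotype": "Kr++",  "order": ["hb", "pdm"],              "clamped_on": "Kr",  "absent": ["cas"],       "persist": true},
    {"genotype": "pdm++", "order": ["hb", "cas"],              "clamped_on": "pdm", "absent": ["Kr"],        "persist": false},
    {"genotype": "cas++", "order": ["hb", "Kr"],               "clamped_on": "cas", "absent": ["pdm"],       "persist": false}
  ]
}
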