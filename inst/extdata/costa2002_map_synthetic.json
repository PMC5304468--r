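{
  "phenomena": [
    {"name": "NF1"},
    {"name": "K-ras"},
    {"name": "N-ras"},
    {"name": "GABA inhibition"},
    {"name": "LTP"},
    {"name": "hippocampal learning"}
  ],
  "edges": [
    {
      "agent": "NF1", "target": "GABA inhibition", "relation": "inhibitory",
      "hypothetical": false,
      "records": [
        {"kind": "neg_int", "observed_relation": "inhibitory", "repetitions": 1}
      ]
    },
    {
      "agent": "K-ras", "target": "LTP", "relation": "excitatory",
      "hypothetical": false,
      "records": [
        {"kind": "neg_int", "observed_relation": "excitatory", "repetitions": 1}
      ]
    },
    {
      "agent": "N-ras", "target": "hippocampal learning", "relation": "no_connection",
      "hypothetical": false,
      "records": [
        {"kind": "neg_int", "observed_relation": "no_connection", "repetitions": 1}
      ]
    },
    {
      "agent": "NF1", "target": "hippocampal learning", "relation": "excitatory",
      "hypothetical": false,
      "records": [
        {"kind": "neg_int", "observed_relation": "excitatory", "repetitions": 1}
      ]
    },
    {
      "agent": "GABA inhibition", "target": "LTP", "relation": "inhibitory",
      "hypothetical": true, "records": []
    },
    {
      "agent": "LTP", "target": "hippocampal learning", "relation": "excitatory",
      "hypothetical": true, "records": []
    }
  ]
}
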