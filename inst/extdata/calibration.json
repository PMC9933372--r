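{
  "method": "least squares on (PLIF QALYs - 13.63, incremental effectiveness - 0.15); residuals close the cost identity exactly",
  "gompertz": {
    "a": 0.0051579396861091,
    "b": 0.1
  },
  "decision_tree_llif_complications": 0.146149413248305,
  "residual_upfront": {
    "LLIF": 4059.23127030289,
    "PLIF": 1523.13354951789
  },
  "achieved": {
    "qaly_llif": 13.4799999997357,
    "qaly_plif": 13.63000000027,
    "cost_llif": 30124,
    "cost_plif": 33003,
    "objective": 3.58419845360573e-19
  }
}
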