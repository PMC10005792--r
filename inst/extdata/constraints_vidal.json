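[
  {
    "parameter": "c_s_dd",
    "profile": "coke|fish|pizza@323K",
    "kind": "fixed",
    "value": 146000000
  },
  {
    "parameter": "c_s_dd",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "c_s_dd",
    "profile": "roll@323K",
    "kind": "fixed",
    "value": 146000000
  },
  {
    "parameter": "c_s_dd",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "coke|fish|pizza@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "roll@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "coke|fish|pizza@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "roll@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "coke|fish|pizza@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "roll@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "c_f_dd",
    "profile": "coke|fish|pizza@323K",
    "kind": "fixed",
    "value": 1250000000
  },
  {
    "parameter": "c_f_dd",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "c_f_dd",
    "profile": "roll@323K",
    "kind": "fixed",
    "value": 1250000000
  },
  {
    "parameter": "c_f_dd",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_f",
    "profile": "coke|fish|pizza@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_f",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_f",
    "profile": "roll@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_f",
    "profile": "watermelon@323K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "coke|fish|pizza@323K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "cherry@323K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "roll@323K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "watermelon@323K",
    "kind": "free"
  }
]
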