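[
  {
    "parameter": "c_s_dd",
    "profile": "bear|phantasia@298K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "bear|phantasia@323K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "balla apple@298K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "balla apple@323K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "balla raspberry@298K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "balla raspberry@323K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "tropifruity|color-rado@298K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "c_s_dd",
    "profile": "tropifruity|color-rado@323K",
    "kind": "shared",
    "group": "c_s_dd=1.46e+08"
  },
  {
    "parameter": "tau_s",
    "profile": "bear|phantasia@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "bear|phantasia@323K",
    "kind": "fixed",
    "value": 2.43e-06
  },
  {
    "parameter": "tau_s",
    "profile": "balla apple@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "balla apple@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "balla raspberry@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "balla raspberry@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "tropifruity|color-rado@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_s",
    "profile": "tropifruity|color-rado@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "bear|phantasia@298K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "bear|phantasia@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "balla apple@298K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "balla apple@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "balla raspberry@298K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "balla raspberry@323K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "tropifruity|color-rado@298K",
    "kind": "free"
  },
  {
    "parameter": "c_i_dd",
    "profile": "tropifruity|color-rado@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "bear|phantasia@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "bear|phantasia@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "balla apple@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "balla apple@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "balla raspberry@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "balla raspberry@323K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "tropifruity|color-rado@298K",
    "kind": "free"
  },
  {
    "parameter": "tau_i",
    "profile": "tropifruity|color-rado@323K",
    "kind": "free"
  },
  {
    "parameter": "c_f_dd",
    "profile": "bear|phantasia@298K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "bear|phantasia@323K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "balla apple@298K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "balla apple@323K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "balla raspberry@298K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "balla raspberry@323K",
    "kind": "free"
  },
  {
    "parameter": "c_f_dd",
    "profile": "tropifruity|color-rado@298K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "c_f_dd",
    "profile": "tropifruity|color-rado@323K",
    "kind": "shared",
    "group": "c_f_dd=1.25e+09"
  },
  {
    "parameter": "tau_f",
    "profile": "bear|phantasia@298K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "bear|phantasia@323K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "balla apple@298K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "balla apple@323K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "balla raspberry@298K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "balla raspberry@323K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "tropifruity|color-rado@298K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "tau_f",
    "profile": "tropifruity|color-rado@323K",
    "kind": "shared",
    "group": "tau_f=5.21e-08"
  },
  {
    "parameter": "a",
    "profile": "bear|phantasia@298K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "bear|phantasia@323K",
    "kind": "fixed",
    "value": 27
  },
  {
    "parameter": "a",
    "profile": "balla apple@298K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "balla apple@323K",
    "kind": "fixed",
    "value": 40.6
  },
  {
    "parameter": "a",
    "profile": "balla raspberry@298K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "balla raspberry@323K",
    "kind": "fixed",
    "value": 37.8
  },
  {
    "parameter": "a",
    "profile": "tropifruity|color-rado@298K",
    "kind": "free"
  },
  {
    "parameter": "a",
    "profile": "tropifruity|color-rado@323K",
    "kind": "fixed",
    "value": 33.1
  }
]
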