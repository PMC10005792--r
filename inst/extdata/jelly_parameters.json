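[
  {
    "brand": "Haribo",
    "jellies": "bear|phantasia",
    "temperature_k": "298",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "2.43e-6",
    "tau_s_unc": "5.2e-7",
    "c_i_dd": "1.00e9",
    "c_i_dd_unc": "1.2e7",
    "tau_i": "4.83e-7",
    "tau_i_unc": "3.9e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "27.0",
    "a_unc": "3.2"
  },
  {
    "brand": "Haribo",
    "jellies": "bear|phantasia",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "2.43e-6",
    "tau_s_unc": null,
    "c_i_dd": "8.02e8",
    "c_i_dd_unc": "4.3e7",
    "tau_i": "3.49e-7",
    "tau_i_unc": "2.6e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "27.0",
    "a_unc": null
  },
  {
    "brand": "Haribo",
    "jellies": "balla apple",
    "temperature_k": "298",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.64e-6",
    "tau_s_unc": "6.9e-8",
    "c_i_dd": "5.20e8",
    "c_i_dd_unc": "3.3e7",
    "tau_i": "3.97e-7",
    "tau_i_unc": "2.9e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "40.6",
    "a_unc": "5.3"
  },
  {
    "brand": "Haribo",
    "jellies": "balla apple",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.50e-6",
    "tau_s_unc": "5.7e-8",
    "c_i_dd": "4.12e8",
    "c_i_dd_unc": "2.9e7",
    "tau_i": "3.00e-7",
    "tau_i_unc": "2.8e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "40.6",
    "a_unc": null
  },
  {
    "brand": "Haribo",
    "jellies": "balla raspberry",
    "temperature_k": "298",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.76e-6",
    "tau_s_unc": "1.3e-7",
    "c_i_dd": "7.86e8",
    "c_i_dd_unc": "3.9e7",
    "tau_i": "4.34e-7",
    "tau_i_unc": "3.0e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "37.8",
    "a_unc": "3.3"
  },
  {
    "brand": "Haribo",
    "jellies": "balla raspberry",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.37e-6",
    "tau_s_unc": "3.6e-8",
    "c_i_dd": "1.78e8",
    "c_i_dd_unc": "2.1e7",
    "tau_i": "2.74e-7",
    "tau_i_unc": "4.2e-8",
    "c_f_dd": "1.02e9",
    "c_f_dd_unc": "3.4e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "37.8",
    "a_unc": null
  },
  {
    "brand": "Haribo",
    "jellies": "tropifruity|color-rado",
    "temperature_k": "298",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.92e-6",
    "tau_s_unc": "5.0e-8",
    "c_i_dd": "7.08e8",
    "c_i_dd_unc": "1.6e7",
    "tau_i": "4.17e-7",
    "tau_i_unc": "1.3e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "33.1",
    "a_unc": "3.7"
  },
  {
    "brand": "Haribo",
    "jellies": "tropifruity|color-rado",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": "6.1e7",
    "tau_s": "1.20e-6",
    "tau_s_unc": "5.8e-8",
    "c_i_dd": "3.61e8",
    "c_i_dd_unc": "2.2e7",
    "tau_i": "3.66e-7",
    "tau_i_unc": "3.3e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": "3.2e8",
    "tau_f": "5.21e-8",
    "tau_f_unc": "2.7e-9",
    "a": "33.1",
    "a_unc": null
  },
  {
    "brand": "Vidal",
    "jellies": "coke|fish|pizza",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": null,
    "tau_s": "1.53e-6",
    "tau_s_unc": "2.8e-8",
    "c_i_dd": "6.98e8",
    "c_i_dd_unc": "6.9e7",
    "tau_i": "2.53e-7",
    "tau_i_unc": "1.6e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": null,
    "tau_f": "3.55e-8",
    "tau_f_unc": "6.3e-9",
    "a": "25.6",
    "a_unc": "1.2"
  },
  {
    "brand": "Vidal",
    "jellies": "cherry",
    "temperature_k": "323",
    "c_s_dd": "1.16e7",
    "c_s_dd_unc": "3.1e6",
    "tau_s": "2.55e-6",
    "tau_s_unc": "5.3e-7",
    "c_i_dd": "1.38e8",
    "c_i_dd_unc": "1.7e7",
    "tau_i": "3.45e-7",
    "tau_i_unc": "2.4e-8",
    "c_f_dd": "9.11e8",
    "c_f_dd_unc": "3.1e7",
    "tau_f": "5.61e-8",
    "tau_f_unc": "2.4e-9",
    "a": "38.4",
    "a_unc": "2.2"
  },
  {
    "brand": "Vidal",
    "jellies": "roll",
    "temperature_k": "323",
    "c_s_dd": "1.46e8",
    "c_s_dd_unc": null,
    "tau_s": "1.26e-6",
    "tau_s_unc": "3.0e-8",
    "c_i_dd": "4.90e8",
    "c_i_dd_unc": "2.0e8",
    "tau_i": "9.32e-8",
    "tau_i_unc": "2.6e-8",
    "c_f_dd": "1.25e9",
    "c_f_dd_unc": null,
    "tau_f": "9.68e-9",
    "tau_f_unc": "6.1e-9",
    "a": "15.1",
    "a_unc": "0.8"
  },
  {
    "brand": "Vidal",
    "jellies": "watermelon",
    "temperature_k": "323",
    "c_s_dd": "2.94e7",
    "c_s_dd_unc": "8.8e7",
    "tau_s": "2.44e-6",
    "tau_s_unc": "4.7e-7",
    "c_i_dd": "1.64e8",
    "c_i_dd_unc": "2.5e7",
    "tau_i": "4.27e-7",
    "tau_i_unc": "8.8e-8",
    "c_f_dd": "8.79e8",
    "c_f_dd_unc": "6.6e7",
    "tau_f": "4.39e-8",
    "tau_f_unc": "6.7e-9",
    "a": "35.0",
    "a_unc": "3.3"
  }
]
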