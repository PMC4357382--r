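{
  "rates": {
    "k_uxp_prod": 0.003,
    "k_cap_feedback": 1e-06,
    "k_pyrg_drain": 0.01,
    "k_seq_on": 0.02,
    "k_seq_off": 0.01,
    "k_act_bind": 0.0001,
    "k_act_unbind": 0.00012,
    "k_tx_active": 0.04,
    "k_tx_basal": 0.0001,
    "k_tl_ca": 0.015,
    "k_capDNAr_bind": 5e-06,
    "k_capDNAr_unbind": 0.0005,
    "k_tx_rep": 0.01,
    "k_tl_rep": 0.01,
    "k_dim_on": 0.001,
    "k_dim_off": 0.001,
    "k_rep_bind": 0.005,
    "k_rep_unbind": 0.0002,
    "k_deg_mRNAca": 0.002,
    "k_deg_mRNAr": 0.002,
    "k_deg_CA": 0.001,
    "k_deg_R": 0.0005,
    "k_deg_R2": 0.0002
  },
  "init": {
    "uxp_range": [50, 200],
    "activator_range": [5, 20],
    "dna_ca_copies": 1,
    "dna_r_copies": 1
  }
}
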