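{
  "NAV15": {
    "description": "Nav1.5 alpha-subunit alone, transiently expressed in COS-7 cells",
    "gating": {
      "vhalf_act": -33.5, "k_act": 6.9,
      "vhalf_inact": -95.8, "k_inact": 8.2,
      "tau_act_max": 0.3, "tau_inact_dep": 1.5,
      "tau_rec": 5.9, "tau_h_vmid": -70, "tau_h_vslope": 10
    },
    "density_ref": {"v_mV": -20, "density_pA_pF": -119},
    "conditioning_mV": -130,
    "solutions": {"na_out_mM": 150, "na_in_mM": 5, "temperature_K": 294.15},
    "cell": {"cm": 20, "rs_residual": 1, "g_leak": 1, "e_leak": -20,
             "noise_sd": 10, "cap_transient_tau": 0.1},
    "sampling_khz": 20
  },
  "NAV15_B1": {
    "description": "Nav1.5 coexpressed with the beta1 auxiliary subunit in COS-7 cells",
    "gating": {
      "vhalf_act": -36.1, "k_act": 7.3,
      "vhalf_inact": -89.8, "k_inact": 6.8,
      "tau_act_max": 0.3, "tau_inact_dep": 1.5,
      "tau_rec": 5.06, "tau_h_vmid": -70, "tau_h_vslope": 10
    },
    "density_ref": {"v_mV": -20, "density_pA_pF": -198},
    "conditioning_mV": -130,
    "solutions": {"na_out_mM": 150, "na_in_mM": 5, "temperature_K": 294.15},
    "cell": {"cm": 20, "rs_residual": 1, "g_leak": 1, "e_leak": -20,
             "noise_sd": 10, "cap_transient_tau": 0.1},
    "sampling_khz": 20
  },
  "HSC_CM": {
    "description": "Human stem cell-derived cardiomyocyte sodium current",
    "gating": {
      "vhalf_act": -40.2, "k_act": 7.4,
      "vhalf_inact": -80.0, "k_inact": 9.2,
      "tau_act_max": 0.3, "tau_inact_dep": 1.5,
      "tau_rec": 5.05, "tau_h_vmid": -70, "tau_h_vslope": 10
    },
    "density_ref": {"v_mV": -30, "density_pA_pF": -186},
    "conditioning_mV": -130,
    "solutions": {"na_out_mM": 150, "na_in_mM": 5, "temperature_K": 294.15},
    "cell": {"cm": 15, "rs_residual": 1, "g_leak": 1, "e_leak": -20,
             "noise_sd": 10, "cap_transient_tau": 0.1},
    "sampling_khz": 10,
    "contaminant": {"g_density": 0.05, "e_k": -85, "vhalf": 20, "k": 8,
                    "tau_inact": 20}
  }
}
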