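{
  "config_version": 1,
  "comment": "Calibrated defaults for the two-plan accelerated race model. Units: activity units, ms, activity units/ms (rates), activity units/ms^2 (accelerations). The 'low' block lists the fields overridden by the low-luminance preset (delayed, weakened exogenous response).",
  "high": {
    "build_mean": 4.0,
    "build_sd": 2.5,
    "build_corr": -0.2,
    "threshold": 1000,
    "efferent_delay_ms": 20,
    "go_latency_mean_ms": 60,
    "go_latency_sd_ms": 15,
    "exo_latency_ms": 80,
    "eri_duration_ms": 25,
    "halt_ms": 10,
    "exo_accel": 1.2,
    "endo_accel": 0.04,
    "endo_decel": 0.4,
    "bias": 0,
    "timeout_ms": 2000
  },
  "low": {
    "exo_latency_ms": 112,
    "exo_accel": 0.8
  }
}
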