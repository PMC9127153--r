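# data.table NSE is used inside compute_ess_table()
.datatable.aware <- TRUE

utils::globalVariables(c(
  "velocity_m_s", "period_s", "diameter_m", "hematocrit", "time_s", "sex"
))
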