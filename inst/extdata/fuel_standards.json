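{
  "schema_version": "1.0",
  "comment": "Biodiesel quality limits. min/max are closed bounds unless the matching *_open flag is true. Units: kv mm2/s at 40C, cn dimensionless, iv g I2/100 g oil, cp degC, density g/cm3, db4plus_pct and c18_3_pct as % of total FAMEs.",
  "standards": {
    "ASTM_D6751": {
      "kv": {"min": 1.9, "max": 6.0},
      "cn": {"min": 47},
      "density": {"min": 0.85, "max": 0.90},
      "cp": {"min": 4, "min_open": true},
      "c18_3_pct": {"max": 12}
    },
    "EN_14214": {
      "kv": {"min": 3.5, "max": 5.0},
      "cn": {"min": 51},
      "iv": {"max": 120},
      "density": {"min": 0.86, "max": 0.90},
      "db4plus_pct": {"max": 10},
      "c18_3_pct": {"max": 12}
    }
  }
}
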