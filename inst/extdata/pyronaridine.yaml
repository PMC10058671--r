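# Minimal PBPK configuration: pyronaridine in the golden hamster.
# Whole blood is the reference matrix; amounts in ng, concentrations ng/mL.
physiology:
  V_total: 102.01      # mL (102.01 g body weight at unit density)
  V_blood: 7.20        # mL
  V_lung: 0.48         # mL
  V_trachea: 0.06      # mL
  Q_co: 1181.28        # mL/h cardiac output
  Q_trachea_fraction: 0.021   # trachea receives 2.1% of cardiac output
parent:
  k_a: 0.03            # 1/h
  CL_F: 0.21           # L/h
  K_lung: 26.06
  K_trachea: 8.67
  K_rest: 5.25e-7
  k_tl: 1.01           # 1/h trachea -> lung
  k_lt: 0.92           # 1/h lung -> trachea
  K_bp: 1
options:
  kind: single
  unit_mode: mass_ng
  analyte: pyronaridine
regimens:
  low:
    dose_per_kg: 180
    body_weight: 0.10201
    n_doses: 3
    interval_tau: 24
  high:
    dose_per_kg: 360
    body_weight: 0.10201
    n_doses: 3
    interval_tau: 24
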