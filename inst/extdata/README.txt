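synthetic_panel.csv — SYNTHETIC person-day panel (41 persons x 7 days) drawn
from the package's generative model (simulate_panel(panel_sim_spec(seed = 20))).
No participant data; for examples only. Columns follow the panel CSV dialect
(see ?read_panel).
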