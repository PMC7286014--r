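# Example 6 MV commissioning summaries

Published-style commissioning summaries for a flattened 6 MV beam
(TPR20,10 = 0.665) on a TrueBeam-class linac, jaw-defined fields, SSD
100 cm, measurement depth 10 cm. Used by the regression tests and the
worked examples.

- `field_widths_6mv.csv` — collimator side at 100 cm and at the 110 cm
  measurement plane, EDGE-measured cross-/in-plane FWHM (cm) and the
  reported equivalent square side `S_clin`.
- `fof_uncorrected_6mv.csv` — uncorrected field output factors per detector
  (CC01 micro-chamber, PFD shielded diode, EFD unshielded diode; EDGE and
  CC13 shown but excluded from the pooled mean/SD/%SD columns).
- `fof_corrected_6mv.csv` — the same after protocol output correction
  factors (the 1 cm row requires correction factors not included here).
- `fof_ifm_6mv.csv` — output factors via the intermediate field method
  (CC13 has no 1 cm entry).
- `fof_mlc_jaw_6mv.csv` — uncorrected output factors for MLC-defined vs
  jaw-defined fields (0.5 cm jaw offset) with their printed ratios.
- `mu_summary_6mv.csv` — calculated monitor-unit summaries (mean, SD, %SD
  across three commissioning datasets) for the cases where the spread was
  largest: the 1 x 1 cm^2 symmetric field and the smallest-target IMRT
  radiosurgery case.
- `edge_k_6mv.csv` — the two EDGE output correction factors quoted for
  this beam (2 x 2 and 3 x 3 cm^2 equivalent squares).

Pooled statistics use the sample (n - 1) standard deviation; %SD is
SD/mean x 100.
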