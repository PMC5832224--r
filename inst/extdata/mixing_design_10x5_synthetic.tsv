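# synthetic 10-sample x 5-tissue mixing design (fractions per sample column)
# each tissue dominates two samples: once at 0.60, once at 0.36; the
# remaining tissues share the rest equally; uniform-baseline RMSE = 0.14
tissue	M01	M02	M03	M04	M05	M06	M07	M08	M09	M10
ADI	0.60	0.10	0.10	0.10	0.10	0.36	0.16	0.16	0.16	0.16
COL	0.10	0.60	0.10	0.10	0.10	0.16	0.36	0.16	0.16	0.16
HEA	0.10	0.10	0.60	0.10	0.10	0.16	0.16	0.36	0.16	0.16
HYP	0.10	0.10	0.10	0.60	0.10	0.16	0.16	0.16	0.36	0.16
KID	0.10	0.10	0.10	0.10	0.60	0.16	0.16	0.16	0.16	0.36
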