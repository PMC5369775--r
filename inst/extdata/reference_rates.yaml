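# General-population outcome rates (Finnish national registers, 2013).
# Preeclampsia subtype fractions are shares of the overall preeclampsia
# rate: severity, and delivery-timing categories (early < 34 wk,
# intermediate 34-36+6 wk, term >= 37 wk; preterm = early + intermediate).
pe: 0.025
severe_frac: 0.24
early_frac: 0.08
intermediate_frac: 0.15
term_frac: 0.77
preterm_frac: 0.23
gh: 0.044
sga: 0.023
gdm: 0.09
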