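# Literature three-pore-model MTAC reference values (mL/min) used only for
# the +/-10% plausibility band in benchmark reports. Human values from the
# standard TPM literature; config data, not asserted results.
urea: 17.0
creatinine: 10.0
glucose: 14.0
sodium: 4.5
phosphate: 7.5
potassium: 15.0
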