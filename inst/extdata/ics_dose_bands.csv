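drug,therapy_class,ics_dose_band
beclometasone_low,ICS,low
beclometasone_medium,ICS,medium
beclometasone_high,ICS,high
budesonide_low,ICS,low
budesonide_medium,ICS,medium
budesonide_high,ICS,high
fluticasone_low,ICS,low
fluticasone_medium,ICS,medium
fluticasone_high,ICS,high
budesonide_formoterol_low,ICS_LABA,low
budesonide_formoterol_medium,ICS_LABA,medium
budesonide_formoterol_high,ICS_LABA,high
fluticasone_salmeterol_low,ICS_LABA,low
fluticasone_salmeterol_medium,ICS_LABA,medium
fluticasone_salmeterol_high,ICS_LABA,high
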