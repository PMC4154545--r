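# Published state-level planning figures for Uttar Pradesh. The modality
# totals were computed from finer-grained (subtype-level) inputs than the
# published site-group tables, so they exceed a group-level recomputation;
# they are used as explicit overrides for the capacity stage.
quantity,value
total_cases,160296
requiring_surgery,74860
requiring_chemotherapy,117172
requiring_radiotherapy,94808
beds_needed,2892
national_cases_2008,948858
national_cases_2016,1220000
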