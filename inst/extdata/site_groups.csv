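# Explicit subtype -> site-group mapping (user-editable; nothing is
# inferred from label text).
subtype,group
cervix uteri,gynecological
corpus uteri,gynecological
ovary,gynecological
larynx,head and neck
lip and oral cavity,head and neck
nasopharynx,head and neck
other pharynx,head and neck
thyroid,head and neck
hodgkin lymphoma,hematological
leukemia,hematological
multiple myeloma,hematological
non-hodgkin lymphoma,hematological
bladder,urological
kidney,urological
prostate,urological
testis,urological
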