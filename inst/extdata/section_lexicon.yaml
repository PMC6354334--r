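# Header lexicon mapping header surface strings to canonical section names.
# Extend or override and pass to match_sections() / the CLI via --lexicon.
主诉: Chief complaint
现病史: History of present illness
既往史: Past medical history
个人史: Personal history
入院情况: Conditions in admission
体格检查: Physical examination
辅助检查: Assistant examination
初步诊断: Preliminary diagnosis
入院诊断: Diagnosis on admission
诊疗经过: Diagnosis and treatment
出院情况: Conditions in discharge
出院诊断: Diagnosis on discharge
出院医嘱: Discharge orders
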