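taxon	copy_number
Enterobacteriaceae	7.0
Lactobacillaceae	5.0
Christensenellaceae	2.5
Bacteroides	5.5
Bifidobacterium	3.5
Odoribacter	3.0
Oscillibacter	2.0
Enterococcus_faecalis	4.0
Faecalibacterium_prausnitzii	5.0
Universal_V4	4.2
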