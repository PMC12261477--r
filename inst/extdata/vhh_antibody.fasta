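>VHH_antibody_wild_type variable domain of an anti-growth-hormone nanobody heavy chain
MQVQLVESGGGLAQAGGSLRLSCAVSGMPEFARAMGWFRQAPGKERELLAAIEGIGATTYYADSVKGRFTISRDDAANTVLLQMNSLKPDDTAVYYCAAAFSVTIPTRARHWVDWGPGTLVTVSSDDDDKSGGGGSHHHHHH
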