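# Reconstructed (synthetic) country scaling factors: back-derived from the
# published country ICER/ROI table relative to the USA reference row.
country,cost_factor,benefit_factor
USA,1,1
UK,0.75,0.65
Germany,0.8,0.75
Canada,0.85,0.8
Australia,0.9,0.8
France,0.85,0.75
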