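# Example scenario: higher peak uptake, response distribution recomputed
# analytically instead of the fixed printed split.
# Keys are flat dotted paths into the parameter bundle; unknown keys error.
uptake.peak_share: 0.875
engine.response_source: analytic
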