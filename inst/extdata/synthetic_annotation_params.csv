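"cell_id","x","y","major_px","minor_px","orientation_deg"
1,48.2,47.7,11.2,7.2,25
2,47.6,48.4,9.5,6.9,-60
3,48.9,47.3,13,7.6,80
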