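# Compendial dissolution run parameters (metadata only)
medium: 0.01 N HCl
volume_ml: 1000
apparatus: USP 2 (paddle)
speed_rpm: 50
temp_c: 37
detection: HPLC (210 nm)
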