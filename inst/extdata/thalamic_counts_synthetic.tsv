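population	excitatory	nominal_count
RTNo	FALSE	727
RTNm	FALSE	727
RTNi	FALSE	1453
VPL	TRUE	1453
VPM	TRUE	1453
POm	TRUE	2906
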