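tube_voltage_kv,hvl_specimen_mm,hvl_al_mm
50,20.1,2.6
60,21.6,3.3
70,22.4,3.9
80,23.9,4.4
90,24.8,4.9
100,25.8,5.4
110,26.6,5.8
120,27.0,6.2
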