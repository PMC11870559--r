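"group","day","ratio"
"treated",0,1.02602945364593
"treated",7,0.158738614164598
"treated",14,0.0283518720799603
"control",0,0.995762560752571
"control",7,23.3617448135779
"control",14,510.580754024663
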