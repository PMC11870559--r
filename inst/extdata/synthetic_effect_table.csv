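"feature_id","beta","is_exhaustion_marker"
"GENE001",0.490984705675221,FALSE
"GENE002",0.234357520018044,FALSE
"GENE003",-0.0539856661082217,FALSE
"GENE004",-0.106439084485603,FALSE
"GENE005",0.579049227519664,FALSE
"GENE006",0.64617742271894,FALSE
"GENE007",0.267323573066157,FALSE
"GENE008",-0.0635173596021398,FALSE
"GENE009",-0.612437707234534,FALSE
"GENE010",-0.560675651080146,FALSE
"GENE011",-0.835962512046452,FALSE
"GENE012",0.23445896489192,FALSE
"GENE013",0.416094953238813,FALSE
"GENE014",0.146510802556107,FALSE
"GENE015",-1.63714291127881,FALSE
"GENE016",-0.0740553755923051,FALSE
"GENE017",-0.464969367637316,FALSE
"GENE018",0.227107175784063,FALSE
"LAG3",-0.178778551865726,TRUE
"PDCD1",-0.0977057342500662,TRUE
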