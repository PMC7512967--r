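"phi","sampen_mean","sampen_sd","n_reps","n_beats"
0,1.28874446284969,0.0418838510327353,300,300
0.05,1.28886278146002,0.0402543884003623,300,300
0.1,1.28464618897637,0.0415196354047528,300,300
0.15,1.28126317132155,0.0403812063126118,300,300
0.2,1.270908514988,0.0441625311108627,300,300
0.25,1.26177823030164,0.0439357673170001,300,300
0.3,1.24617479323844,0.0393059068974701,300,300
0.35,1.23293615877403,0.0448292435795705,300,300
0.4,1.21738223401188,0.044318733607974,300,300
0.45,1.18865755662925,0.0472300584076543,300,300
0.5,1.16389098528374,0.047146490078429,300,300
0.55,1.13563579034088,0.0510148172316283,300,300
0.6,1.09459077551377,0.0521389425630185,300,300
0.65,1.05342049490491,0.0521436648162068,300,300
0.7,0.994735410883372,0.0588700006584139,300,300
0.75,0.928339085312203,0.0660270254907517,300,300
0.8,0.861674019809539,0.0665949529785065,300,300
0.85,0.760669890062495,0.0775067301385242,300,300
0.9,0.623892369204966,0.0898486042565681,300,300
0.925,0.549333994551572,0.0913415691077801,300,300
0.95,0.445950918725507,0.097818745582585,300,300
0.97,0.351311644508368,0.103773418271028,300,300
0.98,0.304646706177068,0.101140289634319,300,300
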