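term,coefficient,se
constant,-5.539,0.54
soy_lecithin,0.406,0.276
soy_oil,-0.081,0.276
duration,-0.249,0.276
lactic_acid,-0.054,0.276
orange_extract,-0.231,0.276
soy_lecithin^2,-0.027,0.250
soy_oil^2,-0.466,0.250
duration^2,-0.410,0.250
lactic_acid^2,0.030,0.250
orange_extract^2,-0.450,0.250
soy_lecithin:soy_oil,-0.057,0.338
soy_lecithin:duration,-0.411,0.338
soy_lecithin:lactic_acid,-0.108,0.338
soy_lecithin:orange_extract,0.948,0.338
soy_oil:duration,-0.156,0.338
soy_oil:lactic_acid,0.006,0.338
soy_oil:orange_extract,-0.468,0.338
duration:lactic_acid,-0.204,0.338
duration:orange_extract,0.132,0.338
lactic_acid:orange_extract,-0.517,0.338
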