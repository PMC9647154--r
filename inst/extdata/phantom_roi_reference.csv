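tissue,ct_mean,corrected_mean,raw_mean
muscle,134,140,-384
muscle,127,126,-441
muscle,134,142,-353
muscle,125,138,-334
muscle,121,129,-435
muscle,131,139,-375
adipose,-112,-108,-128
bladder,191,205,-340
uterus,196,181,-416
rectum,199,199,-380
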