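chain,height,lateral
left,5.47,0.01
left,5.05,-0.26
left,4.22,-0.65
left,3.39,-0.69
left,2.05,-0.45
left,0.48,0.04
right,5.47,0.01
right,4.95,0.48
right,3.95,0.57
right,3.07,0.64
right,2.55,0.62
right,0.48,0.04
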