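"","off range","western range","eastern range"
"off range",-0.1397,0.1077,0.032
"western range",0.257,-0.5077,0.2507
"eastern range",0.1836,1.2906,-1.4743
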