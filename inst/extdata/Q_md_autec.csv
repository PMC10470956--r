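"","south","western range","northwest","northeast","eastern range"
"south",-0.2724,0.2022,0,0,0.0702
"western range",0.1964,-0.8101,0.1676,0.0339,0.4122
"northwest",0,0.1911,-0.6488,0.4464,0.0113
"northeast",0,0.0173,0.8364,-0.9048,0.0511
"eastern range",0.1816,1.6187,0,0.481,-2.2813
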