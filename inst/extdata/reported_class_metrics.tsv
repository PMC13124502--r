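class	precision	recall	f1	support
positive	0.903	0.850	0.875	120
neutral	0.836	0.850	0.843	120
negative	0.880	0.917	0.898	120
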