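video_id	category	valence_mean	valence_sd	arousal_mean	arousal_sd
V01	positive	7.8	0.6	7.2	0.8
V02	positive	8.1	0.5	6.5	0.7
V03	positive	7.5	0.7	6.8	0.9
V04	positive	7.9	0.6	7.5	0.7
V05	positive	7.6	0.8	7.0	0.8
V06	positive	7.7	0.6	6.2	0.8
V07	neutral	5.1	0.4	3.2	0.5
V08	neutral	5.3	0.5	3.5	0.6
V09	neutral	5.0	0.4	3.1	0.5
V10	neutral	4.9	0.5	2.8	0.5
V11	neutral	5.4	0.5	3.3	0.6
V12	neutral	5.2	0.4	3.4	0.5
V13	negative	2.5	0.5	7.8	0.7
V14	negative	2.3	0.4	7.5	0.8
V15	negative	2.8	0.6	7.0	0.8
V16	negative	2.1	0.4	8.0	0.7
V17	negative	2.4	0.5	7.6	0.8
V18	negative	2.6	0.5	7.4	0.7
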