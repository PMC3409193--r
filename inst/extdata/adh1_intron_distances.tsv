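# Published pairwise distance estimates among the concatenated intron
# alignments of 12 primate class-I alcohol-dehydrogenase (ADH1) paralogs
# (human Hum, rhesus macaque Mac, common marmoset Cal), maximum composite
# likelihood, pairwise gap deletion. Mac_ADH1.2 rows are largely absent
# (chimeric/converted gene excluded from the published matrix).
label_a	label_b	distance	variance
Hum_ADH1A	Hum_ADH1B	0.123	0.003
Hum_ADH1A	Hum_ADH1C	0.143	0.004
Hum_ADH1B	Hum_ADH1C	0.139	0.004
Hum_ADH1A	Mac_ADH1.0	0.134	0.005
Hum_ADH1B	Mac_ADH1.0	0.146	0.005
Hum_ADH1C	Mac_ADH1.0	0.155	0.004
Hum_ADH1A	Mac_ADH1.1	0.059	0.002
Hum_ADH1B	Mac_ADH1.1	0.134	0.004
Hum_ADH1C	Mac_ADH1.1	0.153	0.004
Mac_ADH1.0	Mac_ADH1.1	0.143	0.005
Hum_ADH1A	Mac_ADH1.2	NA	0.004
Hum_ADH1B	Mac_ADH1.2	NA	0.003
Hum_ADH1C	Mac_ADH1.2	NA	0.004
Mac_ADH1.0	Mac_ADH1.2	NA	0.005
Mac_ADH1.1	Mac_ADH1.2	NA	0.003
Hum_ADH1A	Mac_ADH1.3	0.139	0.003
Hum_ADH1B	Mac_ADH1.3	0.072	0.003
Hum_ADH1C	Mac_ADH1.3	0.153	0.004
Mac_ADH1.0	Mac_ADH1.3	0.163	0.006
Mac_ADH1.1	Mac_ADH1.3	0.151	0.003
Hum_ADH1A	Mac_ADH1.4	0.152	0.004
Hum_ADH1B	Mac_ADH1.4	0.146	0.005
Hum_ADH1C	Mac_ADH1.4	0.065	0.003
Mac_ADH1.0	Mac_ADH1.4	0.164	0.005
Mac_ADH1.1	Mac_ADH1.4	0.160	0.004
Mac_ADH1.2	Mac_ADH1.4	0.158	NA
Mac_ADH1.3	Mac_ADH1.4	0.158	0.004
Hum_ADH1A	Cal_ADH1.1	0.149	0.004
Hum_ADH1B	Cal_ADH1.1	0.169	0.004
Hum_ADH1C	Cal_ADH1.1	0.171	0.004
Mac_ADH1.0	Cal_ADH1.1	0.129	0.004
Mac_ADH1.1	Cal_ADH1.1	0.158	0.004
Mac_ADH1.2	Cal_ADH1.1	0.178	NA
Mac_ADH1.3	Cal_ADH1.1	0.187	0.004
Mac_ADH1.4	Cal_ADH1.1	0.179	0.005
Hum_ADH1A	Cal_ADH1.2	0.127	0.004
Hum_ADH1B	Cal_ADH1.2	0.154	0.004
Hum_ADH1C	Cal_ADH1.2	0.170	0.004
Mac_ADH1.0	Cal_ADH1.2	0.164	0.004
Mac_ADH1.1	Cal_ADH1.2	0.132	0.004
Mac_ADH1.3	Cal_ADH1.2	0.170	0.004
Mac_ADH1.4	Cal_ADH1.2	0.179	0.005
Cal_ADH1.1	Cal_ADH1.2	0.158	0.004
Hum_ADH1A	Cal_ADH1.3	0.146	0.004
Hum_ADH1B	Cal_ADH1.3	0.124	0.004
Hum_ADH1C	Cal_ADH1.3	0.169	0.004
Mac_ADH1.0	Cal_ADH1.3	0.175	0.006
Mac_ADH1.1	Cal_ADH1.3	0.157	0.005
Mac_ADH1.3	Cal_ADH1.3	0.141	0.004
Mac_ADH1.4	Cal_ADH1.3	0.176	0.005
Cal_ADH1.1	Cal_ADH1.3	0.183	0.005
Cal_ADH1.2	Cal_ADH1.3	0.152	0.004
Hum_ADH1A	Cal_ADH1.4	0.165	0.004
Hum_ADH1B	Cal_ADH1.4	0.161	0.003
Hum_ADH1C	Cal_ADH1.4	0.120	0.004
Mac_ADH1.0	Cal_ADH1.4	0.184	0.005
Mac_ADH1.1	Cal_ADH1.4	0.173	0.004
Mac_ADH1.2	Cal_ADH1.4	0.175	NA
Mac_ADH1.3	Cal_ADH1.4	0.177	0.004
Mac_ADH1.4	Cal_ADH1.4	0.127	0.004
Cal_ADH1.1	Cal_ADH1.4	0.185	0.004
Cal_ADH1.2	Cal_ADH1.4	0.183	0.005
Cal_ADH1.3	Cal_ADH1.4	0.172	0.004
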