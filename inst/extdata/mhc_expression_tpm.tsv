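Gene	Brain_EST	Embryo	Liver	Muscle	Skin	Spleen	Testes
TUBB	21.7	3.1	0.0	0.0	0.0	0.0	0.0
TRIM7.2	97.8	0.0	0.0	3.1	0.0	0.0	0.0
TRIM39	0.0	0.0	2.5	0.0	4.0	6.9	3.3
TRIM27	10.9	3.1	0.0	0.0	0.0	0.0	0.0
Ii	76.1	182.2	323.2	887.5	241.7	4060.4	250.2
Class_I	130.4	6.2	106.9	18.4	31.7	1695.0	110.1
CIITA	0.0	0.0	0.0	0.0	0.0	10.4	0.0
CD1A	0.0	0.0	2.5	0.0	0.0	55.6	0.0
BRD2	21.7	0.0	0.0	0.0	0.0	0.0	0.0
B2M	10.9	0.0	45.8	9.2	27.7	896.1	43.4
Library size	92040	323897	392890	325646	252349	287902	299755
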