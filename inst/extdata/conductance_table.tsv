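figure	response_type	Na	K	KA	KCa	H	CaL	CaT	CAN
2A	Non-accommodating simple spike train	0.02	0.01	0.01	-	0.002	-	-	-
2B	Accommodating simple spike train	0.01	0.001	0.005	-	0.001	-	4.00e-4	-
2C	Single spike	0.01	0.002	0.02	-	-	-	2.00e-4	-
2D	Irregular spiking (rare)	0.02	0.01	0.01	-	0.005	-	1.00e-4	-
3A	LTS with single AP	0.01	0.1	0.1	-	3.58e-5	-	0.005	-
3B	LTS with AP burst	0.011	0.075	0.025	-	3.58e-5	-	0.002	-
3C	AP burst with extended plateau potential	0.004	0.007	0.001	0.001	0.0005	0.001	0.0001	0.00128
3D	AP burst with extended plateau potential	0.004	0.007	0.001	0.001	0.0005	0.001	-	0.00128
3E	AP burst with extended plateau potential	0.004	0.006	0.001	0.001	0.0005	0.001	0.0001	0.00128
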