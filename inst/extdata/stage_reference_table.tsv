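species	stage	mean_esd_mm	sd_esd_mm
Metridia pacifica	C1	0.426	0.035
Metridia pacifica	C2	0.517	0.045
Metridia pacifica	C3	0.666	0.051
Metridia pacifica	C4F	0.921	0.062
Metridia pacifica	C4M	0.872	0.072
Metridia pacifica	C5F	1.229	0.076
Metridia pacifica	C5M	1.073	0.070
Metridia pacifica	C6F	1.726	0.121
Metridia pacifica	C6M	1.146	0.061
Eucalanus bungii	C1	0.779	0.066
Eucalanus bungii	C2	0.995	0.088
Eucalanus bungii	C3	1.475	0.111
Eucalanus bungii	C4F	2.089	0.116
Eucalanus bungii	C4M	2.066	0.141
Eucalanus bungii	C5F	2.865	0.222
Eucalanus bungii	C5M	2.798	0.187
Eucalanus bungii	C6F	3.827	0.276
Eucalanus bungii	C6M	2.971	0.095
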