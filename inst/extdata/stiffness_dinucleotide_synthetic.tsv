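context	shift0	slide0	rise0	tilt0	roll0	twist0	theta_shift_shift	theta_shift_slide	theta_shift_rise	theta_shift_tilt	theta_shift_roll	theta_shift_twist	theta_slide_slide	theta_slide_rise	theta_slide_tilt	theta_slide_roll	theta_slide_twist	theta_rise_rise	theta_rise_tilt	theta_rise_roll	theta_rise_twist	theta_tilt_tilt	theta_tilt_roll	theta_tilt_twist	theta_roll_roll	theta_roll_twist	theta_twist_twist
AA	-0.05	-0.21	3.27	-1.4	0.7	35.3	2.2	0	0	0.039243	0	0	4.5	0.980752	0	0	0	9.5	0	0	0	0.07	0	0	0.06	-0.006364	0.03
AC	0.13	-0.54	3.36	-0.4	0.7	31.8	1.29	0	0	0.023277	0	0	2.8	0.666446	0	0	0	7.05	0	0	0	0.042	0	0	0.033	-0.005024	0.034
AG	0.07	-0.25	3.34	-1.7	4.5	32.3	1.22	0	0	0.022091	0	0	2.47	0.598714	0	0	0	6.45	0	0	0	0.04	0	0	0.028	-0.004274	0.029
AT	0	-0.56	3.31	0	1.1	29.8	1.55	0	0	0.027839	0	0	3.35	0.766763	0	0	0	7.8	0	0	0	0.05	0	0	0.04	-0.00545	0.033
CA	0.09	0.48	3.45	0.5	5.9	34.5	1.05	0	0	0.016837	0	0	1.62	0.422617	0	0	0	4.9	0	0	0	0.027	0	0	0.02	-0.002683	0.016
CC	-0.05	-0.22	3.42	0.1	3.6	33.7	1.43	0	0	0.022689	0	0	2.24	0.558999	0	0	0	6.2	0	0	0	0.036	0	0	0.027	-0.003974	0.026
CG	0	0.57	3.39	0	4.6	36.1	1.05	0	0	0.016523	0	0	1.78	0.433861	0	0	0	4.7	0	0	0	0.026	0	0	0.021	-0.002834	0.017
GA	-0.02	-0.03	3.38	-1.5	1.9	36.9	1.38	0	0	0.0229	0	0	2.45	0.598592	0	0	0	6.5	0	0	0	0.038	0	0	0.028	-0.003969	0.025
GC	0	-0.07	3.38	0	0.9	33.6	1.32	0	0	0.021799	0	0	2.55	0.62462	0	0	0	6.8	0	0	0	0.036	0	0	0.03	-0.004347	0.028
TA	0	0.05	3.42	0	3.3	37.8	0.98	0	0	0.015336	0	0	1.55	0.384992	0	0	0	4.25	0	0	0	0.024	0	0	0.018	-0.002381	0.014
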