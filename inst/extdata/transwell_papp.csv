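cell_line,additive,additive_conc_umol_L,direction,papp_1e6_cm_s,papp_sd_1e6_cm_s
control,enzalutamide,0,A2B,1.73,0.73
control,enzalutamide,0,B2A,1.66,0.06
MDR1,enzalutamide,0,A2B,0.641,0.028
MDR1,enzalutamide,0,B2A,12.8,0.6
control,enzalutamide,0.3,A2B,1.39,0.20
control,enzalutamide,0.3,B2A,1.85,0.31
MDR1,enzalutamide,0.3,A2B,0.725,0.043
MDR1,enzalutamide,0.3,B2A,12.4,0.8
control,enzalutamide,1,A2B,1.47,0.14
control,enzalutamide,1,B2A,1.94,0.13
MDR1,enzalutamide,1,A2B,0.851,0.081
MDR1,enzalutamide,1,B2A,13.4,0.4
control,enzalutamide,3,A2B,1.68,0.13
control,enzalutamide,3,B2A,2.02,0.10
MDR1,enzalutamide,3,A2B,1.25,0.26
MDR1,enzalutamide,3,B2A,12.1,0.9
control,enzalutamide,10,A2B,2.09,0.07
control,enzalutamide,10,B2A,2.20,0.10
MDR1,enzalutamide,10,A2B,1.41,0.08
MDR1,enzalutamide,10,B2A,11.0,0.6
control,enzalutamide,30,A2B,2.42,0.24
control,enzalutamide,30,B2A,2.56,0.19
MDR1,enzalutamide,30,A2B,2.11,0.09
MDR1,enzalutamide,30,B2A,7.85,0.28
control,enzalutamide,50,A2B,2.22,0.21
control,enzalutamide,50,B2A,2.63,0.32
MDR1,enzalutamide,50,A2B,2.73,0.12
MDR1,enzalutamide,50,B2A,7.22,0.18
control,M1,0,A2B,1.39,0.09
control,M1,0,B2A,1.66,0.23
MDR1,M1,0,A2B,0.683,0.105
MDR1,M1,0,B2A,15.6,1.2
control,M1,0.3,A2B,1.22,0.06
control,M1,0.3,B2A,1.62,0.22
MDR1,M1,0.3,A2B,0.807,0.032
MDR1,M1,0.3,B2A,13.8,1.1
control,M1,1,A2B,1.31,0.06
control,M1,1,B2A,1.62,0.03
MDR1,M1,1,A2B,0.670,0.029
MDR1,M1,1,B2A,14.0,1.2
control,M1,3,A2B,1.39,0.05
control,M1,3,B2A,1.44,0.13
MDR1,M1,3,A2B,0.725,0.011
MDR1,M1,3,B2A,13.9,0.4
control,M1,10,A2B,1.36,0.11
control,M1,10,B2A,1.36,0.12
MDR1,M1,10,A2B,0.626,0.033
MDR1,M1,10,B2A,13.6,1.0
control,M1,30,A2B,1.43,0.06
control,M1,30,B2A,1.46,0.13
MDR1,M1,30,A2B,0.715,0.045
MDR1,M1,30,B2A,13.1,0.4
control,M1,80,A2B,1.43,0.10
control,M1,80,B2A,1.47,0.13
MDR1,M1,80,A2B,0.623,0.035
MDR1,M1,80,B2A,13.3,0.9
control,M2,0,A2B,1.39,0.09
control,M2,0,B2A,1.66,0.23
MDR1,M2,0,A2B,0.683,0.105
MDR1,M2,0,B2A,15.6,1.2
control,M2,0.1,A2B,1.45,0.04
control,M2,0.1,B2A,1.54,0.08
MDR1,M2,0.1,A2B,0.727,0.088
MDR1,M2,0.1,B2A,14.1,0.2
control,M2,0.3,A2B,1.83,0.09
control,M2,0.3,B2A,2.03,0.15
MDR1,M2,0.3,A2B,0.723,0.170
MDR1,M2,0.3,B2A,13.4,1.0
control,M2,1,A2B,1.38,0.13
control,M2,1,B2A,1.46,0.10
MDR1,M2,1,A2B,1.01,0.02
MDR1,M2,1,B2A,12.1,0.6
control,M2,3,A2B,1.54,0.11
control,M2,3,B2A,1.64,0.12
MDR1,M2,3,A2B,1.89,0.02
MDR1,M2,3,B2A,11.0,0.8
control,M2,10,A2B,1.51,0.11
control,M2,10,B2A,1.66,0.07
MDR1,M2,10,A2B,2.89,0.17
MDR1,M2,10,B2A,8.40,0.38
control,M2,25,A2B,1.68,0.05
control,M2,25,B2A,1.73,0.11
MDR1,M2,25,A2B,2.83,0.12
MDR1,M2,25,B2A,6.19,0.25
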