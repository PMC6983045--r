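# solute_name: 6-phenylpyridazin-3(2H)-one (PPD)
# cosolvent_name: DMSO
# solvent_name: water
# pressure_MPa: 0.1
m,T_K,x_e
0.0,298.2,5.82e-06
0.0,303.2,6.94e-06
0.0,308.2,8.42e-06
0.0,313.2,1.02e-05
0.0,318.2,1.30e-05
0.1,298.2,1.81e-05
0.1,303.2,2.13e-05
0.1,308.2,2.53e-05
0.1,313.2,3.03e-05
0.1,318.2,3.79e-05
0.2,298.2,5.47e-05
0.2,303.2,6.31e-05
0.2,308.2,7.54e-05
0.2,313.2,8.78e-05
0.2,318.2,1.08e-04
0.3,298.2,1.69e-04
0.3,303.2,1.91e-04
0.3,308.2,2.26e-04
0.3,313.2,2.56e-04
0.3,318.2,3.05e-04
0.4,298.2,5.05e-04
0.4,303.2,5.71e-04
0.4,308.2,6.50e-04
0.4,313.2,7.40e-04
0.4,318.2,8.68e-04
0.5,298.2,1.54e-03
0.5,303.2,1.73e-03
0.5,308.2,1.93e-03
0.5,313.2,2.17e-03
0.5,318.2,2.49e-03
0.6,298.2,4.68e-03
0.6,303.2,5.14e-03
0.6,308.2,5.68e-03
0.6,313.2,6.27e-03
0.6,318.2,7.08e-03
0.7,298.2,1.48e-02
0.7,303.2,1.56e-02
0.7,308.2,1.69e-02
0.7,313.2,1.84e-02
0.7,318.2,2.04e-02
0.8,298.2,4.34e-02
0.8,303.2,4.62e-02
0.8,308.2,4.96e-02
0.8,313.2,5.33e-02
0.8,318.2,5.76e-02
0.9,298.2,1.32e-01
0.9,303.2,1.40e-01
0.9,308.2,1.47e-01
0.9,313.2,1.56e-01
0.9,318.2,1.65e-01
1.0,298.2,4.00e-01
1.0,303.2,4.16e-01
1.0,308.2,4.32e-01
1.0,313.2,4.49e-01
1.0,318.2,4.67e-01
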