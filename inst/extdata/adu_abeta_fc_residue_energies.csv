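chain,resno,resid,energy
H,65,LYS,-14.36
H,105,ARG,-10.95
H,59,TYR,-10.04
H,108,PRO,-7.19
L,92,TYR,-17.77
L,94,THR,-15.08
L,93,SER,-13.42
L,1,ASP,-9.35
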