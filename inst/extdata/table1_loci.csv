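locus,pid_sibs,N,Na,AR,Ho,He,FNA,GE,Fis
F124,0.52,8,3,3.00,0.63,0.57,0.03,0.14,0.11
FCA031,0.63,8,2,2.00,0.38,0.43,0.00,0.15,0.06
FCA045,0.50,8,3,3.94,0.63,0.53,-0.04,0.16,-0.03
FCA075,0.46,8,4,3.94,0.75,0.67,-0.07,0.25,-0.10
FCA096,0.42,8,5,4.94,0.88,0.75,-0.03,0.37,-0.01
FCA117,0.55,8,2,2.94,0.50,0.50,-0.01,0.07,0.05
FCA126,0.49,8,3,3.00,0.88,0.57,-0.11,0.16,-0.19
FCA391,0.50,7,4,4.00,0.86,0.64,-0.11,0.27,-0.18
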