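# Mean DSSP-class occupancy per residue for single CATCH 11-mer peptides
# (replica-exchange sampling, 310 K trajectories); helix = 3-10 + alpha + pi.
peptide,residue,helix,bend,turn,coil
6K,1,0.23,0.00,0.29,0.48
6K,2,0.39,0.00,0.32,0.28
6K,3,0.47,0.18,0.24,0.09
6K,4,0.50,0.19,0.23,0.08
6K,5,0.48,0.18,0.24,0.10
6K,6,0.50,0.21,0.22,0.06
6K,7,0.55,0.13,0.27,0.05
6K,8,0.48,0.20,0.26,0.06
6K,9,0.43,0.16,0.32,0.09
6K,10,0.27,0.00,0.31,0.41
6K,11,0.12,0.00,0.18,0.70
6E,1,0.24,0.00,0.22,0.54
6E,2,0.47,0.00,0.27,0.27
6E,3,0.62,0.08,0.23,0.07
6E,4,0.66,0.09,0.21,0.04
6E,5,0.69,0.07,0.18,0.07
6E,6,0.72,0.07,0.19,0.03
6E,7,0.75,0.04,0.18,0.03
6E,8,0.74,0.04,0.19,0.02
6E,9,0.66,0.04,0.26,0.04
6E,10,0.46,0.00,0.39,0.16
6E,11,0.28,0.00,0.34,0.39
6D,1,0.20,0.00,0.19,0.61
6D,2,0.37,0.00,0.25,0.37
6D,3,0.54,0.10,0.24,0.12
6D,4,0.60,0.09,0.25,0.06
6D,5,0.63,0.09,0.21,0.08
6D,6,0.64,0.09,0.22,0.05
6D,7,0.63,0.07,0.21,0.09
6D,8,0.60,0.10,0.25,0.05
6D,9,0.50,0.09,0.30,0.12
6D,10,0.34,0.00,0.35,0.31
6D,11,0.19,0.00,0.29,0.52
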