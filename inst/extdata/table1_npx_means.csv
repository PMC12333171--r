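protein,section,med,pbmc,rmsc,coc,d3,sub1,sub2,sub3,sub4
EGF,a,5.08,5.33,2.33,2.06,1.65,-0.26,2.75,3.01,3.42
PDGF-A,a,5.95,6.05,3.24,3.28,2.78,-0.11,2.71,2.67,3.16
PDGF-B,a,6.17,6.33,3.37,3.52,3.00,-0.16,2.80,2.65,3.17
TCN2,a,8.76,8.97,6.72,7.01,6.51,-0.21,2.04,1.76,2.26
STIP1,a,5.17,5.58,3.67,3.61,3.07,-0.41,1.50,1.56,2.10
SRC,a,5.29,5.60,4.17,4.59,4.83,-0.30,1.13,0.71,0.46
GLO1,a,3.03,2.20,2.27,2.40,2.55,0.83,0.76,0.63,0.48
MMP7,b,5.20,6.35,5.18,6.88,5.37,1.68,0.54,1.70,1.52
CCL24,b,5.54,8.20,5.46,9.06,4.78,3.52,0.86,3.61,4.29
TNF,b,0.55,2.43,0.90,2.08,0.86,1.52,-0.35,1.18,1.21
MPO,b,2.52,3.84,2.46,4.02,2.52,1.51,0.18,1.56,1.50
CCL4,b,1.10,4.77,1.54,4.25,1.02,3.15,-0.52,2.71,3.24
CD5,b,1.04,2.32,1.19,2.29,1.28,1.25,-0.02,1.11,1.01
TR-AP,b,4.02,5.87,3.70,5.39,3.54,1.37,-0.48,1.69,1.85
AZU1,b,2.50,4.96,2.50,5.10,2.70,2.60,0.14,2.60,2.40
GZMA,b,1.03,1.93,1.36,2.12,1.54,1.09,0.19,0.76,0.59
IL-1ra,b,0.08,3.48,0.52,4.20,0.72,4.12,0.71,3.68,3.48
LOX-1,b,1.01,2.88,0.86,2.95,0.99,1.94,0.07,2.09,1.95
CTSS,b,1.51,2.57,2.10,3.30,2.34,1.79,0.73,1.20,0.96
TNF-R2,b,5.08,5.60,4.97,5.55,4.91,0.47,-0.05,0.58,0.64
CCL3,b,3.28,6.42,2.86,5.13,2.43,1.85,-1.28,2.28,2.70
IL16,b,0.91,1.27,0.81,1.49,0.95,0.58,0.22,0.68,0.54
GNLY,b,3.40,4.49,3.51,5.23,2.76,1.83,0.74,1.72,2.47
CXCL16,b,4.60,5.29,4.70,5.59,4.55,0.98,0.29,0.88,1.04
CHI3L1,b,5.49,6.10,5.66,6.44,5.98,0.95,0.34,0.78,0.46
KYNU,b,1.45,1.50,1.16,1.81,1.43,0.36,0.31,0.64,0.37
CCL17,b,4.92,5.30,5.24,5.82,4.42,0.90,0.52,0.57,1.40
MSR1,b,1.12,1.39,1.22,1.56,1.22,0.44,0.17,0.34,0.34
STC1,b,0.61,0.86,2.83,4.04,3.49,3.44,3.18,1.21,0.55
TIMP1,c,9.87,10.23,10.82,10.66,10.01,0.14,-0.22,-0.81,-0.65
CCL17,c,4.92,5.30,5.24,5.82,4.42,-0.50,-0.88,-0.83,-1.40
SAA4,c,8.43,8.47,8.44,8.49,8.20,-0.23,-0.28,-0.24,-0.30
CCL19,c,2.47,2.69,2.72,2.76,2.02,-0.45,-0.67,-0.70,-0.75
PAI,c,8.66,8.84,9.43,9.14,8.81,0.14,-0.04,-0.62,-0.33
CXCL11,c,2.16,1.69,2.02,2.19,1.12,-1.04,-0.57,-0.90,-1.07
SNAP29,c,8.16,8.43,8.13,8.19,6.17,-2.00,-2.27,-1.96,-2.03
SPINK1,c,2.71,2.92,2.67,2.94,1.72,-0.99,-1.20,-0.95,-1.21
TNFRSF13B,c,3.54,3.54,3.43,3.64,3.01,-0.54,-0.53,-0.42,-0.64
ADM,c,1.55,1.01,4.79,5.58,2.68,1.13,1.67,-2.11,-2.90
OPG,d,2.66,2.69,6.60,7.56,8.13,5.47,5.44,1.53,0.57
ANGPTL4,d,3.40,3.58,8.69,8.78,9.86,6.46,6.28,1.17,1.07
TNFRSF12A,d,0.51,0.66,2.81,2.99,3.49,2.99,2.83,0.68,0.51
SPON1,d,1.94,1.76,2.73,3.07,4.98,3.04,3.22,2.25,1.91
Gal-1,d,1.75,2.12,3.91,4.04,5.34,3.58,3.22,1.42,1.30
NRP2,d,1.74,2.34,2.79,3.45,3.56,1.82,1.22,0.77,0.11
CSTB,d,5.41,5.69,5.84,6.13,6.48,1.07,0.79,0.64,0.35
FAP,d,3.82,4.03,4.24,4.40,4.66,0.84,0.62,0.41,0.25
DKK3,d,4.54,4.70,5.80,6.05,6.89,2.34,2.19,1.09,0.84
A2-MRAP,d,2.92,3.24,3.20,3.62,4.44,1.52,1.20,1.25,0.82
RGMB,d,1.16,1.01,2.67,3.06,3.87,2.72,2.87,1.20,0.82
MFGE8,d,3.42,3.56,7.36,7.74,8.80,5.38,5.24,1.44,1.05
IL6,d,1.29,3.70,9.65,11.63,11.89,10.60,8.19,2.23,0.25
THY1,d,2.75,3.12,6.61,7.14,7.84,5.09,4.72,1.23,0.70
N2DL-2,d,1.21,0.72,1.89,2.25,2.49,1.29,1.78,0.61,0.24
IDUA,d,-0.22,-0.41,1.43,1.77,2.64,2.86,3.04,1.20,0.86
AXL,d,8.52,8.64,10.01,10.16,10.56,2.04,1.92,0.55,0.39
CTSF,d,1.29,1.05,1.61,1.98,2.04,0.75,0.99,0.43,0.06
FAS,d,5.80,6.03,7.17,7.50,7.99,2.19,1.96,0.82,0.49
IL15,d,1.37,2.10,3.23,3.28,3.79,2.42,1.69,0.56,0.51
SKR3,d,1.07,1.07,1.46,1.82,2.11,1.04,1.05,0.66,0.30
Upa,d,4.29,4.42,9.42,9.17,11.27,6.98,6.85,1.85,2.09
LTBR,d,2.88,2.95,4.07,4.47,4.74,1.86,1.79,0.67,0.27
GAS6,d,8.72,8.98,9.09,9.51,10.99,2.27,2.02,1.90,1.48
GDNF,d,1.86,1.35,3.30,3.96,4.95,3.09,3.60,1.65,0.99
FS,d,2.83,2.51,5.72,5.75,7.25,4.41,4.73,1.53,1.50
SCF,d,2.41,2.39,3.07,3.27,3.54,1.13,1.15,0.47,0.27
CKAP4,d,2.77,2.87,4.07,4.80,7.58,4.81,4.71,3.51,2.78
PDGF-RA,d,1.36,1.19,1.58,1.82,2.87,1.51,1.68,1.29,1.05
Gal-3,d,4.24,4.49,4.82,5.01,5.56,1.32,1.07,0.74,0.55
PVR,d,1.75,2.07,2.14,2.43,2.59,0.85,0.52,0.45,0.16
ROBO1,d,2.66,2.78,3.10,3.33,3.76,1.09,0.97,0.65,0.42
PD-L1,d,1.41,1.51,1.80,2.01,2.36,0.95,0.85,0.56,0.35
C1QTNF1,d,8.18,8.37,8.63,9.95,9.85,1.67,1.48,1.22,-0.10
NMNAT1,d,1.69,2.26,1.87,2.66,3.57,1.88,1.31,1.70,0.91
ADA,d,2.51,3.12,2.95,3.07,3.41,0.90,0.29,0.46,0.34
JAM-B,d,0.80,1.01,0.99,1.27,1.42,0.62,0.41,0.43,0.15
FSTL3,d,1.90,1.89,2.02,2.10,2.67,0.77,0.78,0.65,0.57
BLVRB,d,2.68,3.07,2.88,3.07,3.88,1.21,0.81,1.01,0.81
EZR,d,0.52,0.69,0.67,1.13,1.27,0.75,0.59,0.60,0.15
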