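# Airway generation surface areas computed from the Weibel symmetric model A
# morphometry (diameter/length per generation, count = 2^generation),
# treating each airway as a cylinder: area_cm2 = pi * diameter * length * count.
# Synthetic stand-in geometry: not the (unpublished) morphometry table behind
# any specific literature total.
generation,diameter_cm,length_cm,count,area_cm2
0,1.8,12,1,67.86
1,1.22,4.76,2,36.49
2,0.83,1.9,4,19.82
3,0.56,0.76,8,10.7
4,0.45,1.27,16,28.73
5,0.35,1.07,32,37.65
6,0.28,0.9,64,50.67
7,0.23,0.76,128,70.29
8,0.186,0.64,256,95.74
9,0.154,0.54,512,133.76
10,0.13,0.46,1024,192.38
11,0.109,0.39,2048,273.51
12,0.095,0.33,4096,403.41
13,0.082,0.27,8192,569.79
14,0.074,0.23,16384,876.05
15,0.066,0.2,32768,1358.86
16,0.06,0.165,65536,2038.29
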