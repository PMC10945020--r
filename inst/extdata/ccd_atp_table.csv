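treatment,soy_lecithin,soy_oil,duration,lactic_acid,orange_extract,atp_measured,atp_sd,atp_predicted,centre_point
1,3.33,1.875,75,292.5,0.28,-7.54,0.44,-5.54,TRUE
2,3.33,1.875,75,337.5,0.28,-6.85,0.05,-5.53,FALSE
3,4.44,1.250,90,270.0,0.42,-4.84,0.13,-4.62,FALSE
4,3.33,1.875,75,247.5,0.28,-5.49,0.45,-5.31,FALSE
5,2.22,2.500,90,315.0,0.13,-4.62,0.03,-5.40,FALSE
6,3.33,1.875,75,292.5,0.28,-4.92,0.00,-5.54,TRUE
7,2.22,2.500,60,315.0,0.42,-8.66,0.00,-9.33,FALSE
8,1.11,1.875,75,292.5,0.27,-8.19,0.98,-6.46,FALSE
9,3.33,1.875,105,292.5,0.28,-8.04,0.98,-7.68,FALSE
10,3.33,1.875,45,292.5,0.28,-7.82,0.48,-6.68,FALSE
11,3.33,1.875,75,292.5,0.28,-4.85,0.43,-5.54,TRUE
12,2.22,1.250,90,315.0,0.41,-7.62,0.33,-8.18,FALSE
13,4.44,2.500,60,315.0,0.13,-4.85,0.06,-5.33,FALSE
14,4.44,2.500,60,270.0,0.43,-5.30,0.13,-5.19,FALSE
15,4.44,1.250,60,315.0,0.42,-4.99,0.11,-5.24,FALSE
16,2.22,1.250,90,270.0,0.13,-6.14,0.01,-6.71,FALSE
17,3.33,3.125,75,292.5,0.28,-8.17,0.98,-7.57,FALSE
18,4.44,1.250,90,315.0,0.13,-7.63,0.16,-7.99,FALSE
19,2.22,1.250,60,315.0,0.13,-4.90,0.17,-5.95,FALSE
20,4.44,2.500,90,315.0,0.43,-7.92,0.81,-7.91,FALSE
21,2.22,1.250,60,270.0,0.41,-7.68,0.68,-8.14,FALSE
22,4.44,1.250,60,270.0,0.13,-7.15,0.17,-7.42,FALSE
23,3.33,1.875,75,292.5,0.57,-7.95,0.66,-7.80,FALSE
24,5.55,1.875,75,292.5,0.28,-4.60,0.05,-4.84,FALSE
25,2.22,2.500,90,270.0,0.42,-7.95,0.50,-8.14,FALSE
26,3.33,1.875,75,292.5,0.28,-4.90,0.01,-5.54,TRUE
27,4.44,2.500,90,270.0,0.13,-7.94,0.40,-7.95,FALSE
28,3.33,1.875,75,292.5,0.28,-4.37,0.14,-5.54,TRUE
29,3.33,1.875,75,292.5,0.28,-5.15,0.27,-5.54,TRUE
30,2.22,2.500,60,270.0,0.13,-5.61,0.03,-6.30,FALSE
31,3.33,1.875,75,292.5,-0.01,-8.23,1.13,-6.88,FALSE
32,3.33,0.625,75,292.5,0.27,-8.14,0.78,-7.24,FALSE
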