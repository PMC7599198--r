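"E@P","A@P","I@P","M@P","E@T","A@T","I@T","M@T","E@S","A@S","I@S","M@S"
1,-0.38,0.42,-0.25,0.64,-0.29,0.38,-0.22,0.45,0.04,0.33,-0.21
-0.38,1,-0.21,0.54,-0.15,0.66,-0.09,0.51,-0.05,0.38,-0.13,0.37
0.42,-0.21,1,-0.54,0.26,-0.19,0.56,-0.33,0.12,-0.03,0.35,-0.44
-0.25,0.54,-0.54,1,-0.05,0.44,-0.19,0.66,0.1,0.14,-0.18,0.58
0.64,-0.15,0.26,-0.05,1,-0.25,0.59,0.06,0.5,0.08,0.41,-0.01
-0.29,0.66,-0.19,0.44,-0.25,1,-0.14,0.62,-0.05,0.3,-0.14,0.41
0.38,-0.09,0.56,-0.19,0.59,-0.14,1,-0.05,0.36,0.09,0.45,-0.1
-0.22,0.51,-0.33,0.66,0.06,0.62,-0.05,1,0.17,0.16,-0.13,0.62
0.45,-0.05,0.12,0.1,0.5,-0.05,0.36,0.17,1,0.02,0.43,0.06
0.04,0.38,-0.03,0.14,0.08,0.3,0.09,0.16,0.02,1,0.16,0.04
0.33,-0.13,0.35,-0.18,0.41,-0.14,0.45,-0.13,0.43,0.16,1,-0.37
-0.21,0.37,-0.44,0.58,-0.01,0.41,-0.1,0.62,0.06,0.04,-0.37,1
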