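"model","q2","N","SEP","SEE","r2_ncv","F","r2_test","S","E","H","D","A"
"CoMFA-SE",0.537,6,0.544,0.067,0.993,525.4,0.865,0.412,0.588,NA,NA,NA
"CoMSIA-SE",0.566,7,0.539,0.101,0.985,193,0.002,0.299,0.701,NA,NA,NA
"CoMSIA-SEHA",0.674,6,0.456,0.119,0.978,161.3,0.79,0.174,0.335,0.215,NA,0.276
"CoMSIA-SEA",0.651,5,0.462,0.151,0.963,118.7,0.76,0.245,0.395,NA,NA,0.36
"CoMSIA-SEDA",0.601,7,0.517,0.103,0.984,185.5,0.816,0.229,0.324,NA,0.19,0.257
"CoMSIA-SD",0.551,6,0.536,0.217,0.926,46.2,0.347,0.47,NA,NA,0.53,NA
"CoMSIA-SHD",0.561,9,0.57,0.095,0.988,172.1,0.237,0.312,NA,0.398,0.289,NA
"CoMSIA-EHA",0.598,6,0.507,0.136,0.971,123,0.765,NA,0.427,0.299,NA,0.274
"CoMSIA-EHDA",0.508,7,0.574,0.111,0.982,160.3,0.716,NA,0.375,0.261,0.156,0.208
"CoMSIA-ALL",0.669,6,0.46,0.101,0.984,225.9,0.918,0.165,0.279,0.181,0.159,0.215
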