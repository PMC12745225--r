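** SYNTHETIC EyeLink-ASCII excerpt (generated, not recorded)
MSG	1000 TRIALID saccadic_1
SSACC R  1241
ESACC R  1241 1310 69 834.1 538.6 1410.8 790.7 17.0 384
EFIX R   1311 1610 299 1410.8 790.7 1100
SSACC R  1862
ESACC R  1862 1923 61 1160.1 382.3 647.6 439.7 13.9 357
EFIX R   1924 2223 299 647.6 439.7 1100
SSACC R  2710
ESACC R  2710 2732 22 549.3 830.3 1023.1 229.9 20.6 431
EFIX R   2733 3032 299 1023.1 229.9 1100
SSACC R  3265
ESACC R  3265 3338 73 1056.3 449.7 1234.6 382.7 5.1 229
EFIX R   3339 3638 299 1234.6 382.7 1100
SSACC R  4174
ESACC R  4174 4236 62 1088.3 295.3 1003.6 845.3 15.0 379
EFIX R   4237 4536 299 1003.6 845.3 1100
SSACC R  4776
ESACC R  4776 4817 41 1075.7 466.8 1241.9 787.4 9.7 266
EFIX R   4818 5117 299 1241.9 787.4 1100
SSACC R  5588
ESACC R  5588 5664 76 1195.9 684.9 1475.0 409.1 10.6 269
EFIX R   5665 5964 299 1475.0 409.1 1100
SSACC R  6542
ESACC R  6542 6586 44 1331.9 593.2 1379.9 474.2 3.5 215
EFIX R   6587 6886 299 1379.9 474.2 1100
SSACC R  7460
ESACC R  7460 7540 80 1409.8 409.7 743.8 546.8 18.3 425
EFIX R   7541 7840 299 743.8 546.8 1100
SSACC R  8407
ESACC R  8407 8467 60 657.0 391.6 658.9 728.0 9.1 271
EFIX R   8468 8767 299 658.9 728.0 1100
SSACC R  9098
ESACC R  9098 9171 73 1280.4 628.1 1258.8 435.9 5.2 190
EFIX R   9172 9471 299 1258.8 435.9 1100
SSACC R  10054
ESACC R  10054 10107 53 467.5 492.5 590.3 406.3 4.0 179
EFIX R   10108 10407 299 590.3 406.3 1100
ESACC R  9000 9040 40 . . 900.0 500.0 2.0 150.0
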