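"id","batch","age","sex","f1","f2","f3"
"F01","1.5T",80.4,"female",2.5894,3.0792,1836
"F02","1.5T",69.1,"male",2.6506,3.0883,1854.3
"F03","1.5T",77,"female",2.5668,2.7026,1850.6
"F04","1.5T",77.4,"male",2.4706,2.9612,1772.8
"F05","3T",72.1,"female",2.6152,2.886,1891.2
"F06","3T",77.4,"male",2.5411,2.9214,1743
"F07","3T",71.1,"female",2.5874,2.8284,1866.3
"F08","3T",68.7,"male",2.7379,2.7619,1928.9
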