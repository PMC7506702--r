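compression,owlxml,rdfxml,functional,manchester,turtle
plain,3915.00,6388.74,1480.74,1968.00,4984.95
exi,668.11,645.63,NA,NA,NA
hdt,NA,NA,NA,NA,3534.42
lzma,814.68,994.05,568.32,641.26,880.42
gzip,796.42,996.89,542.32,619.11,869.32
deflate,784.42,984.89,530.32,607.11,857.32
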