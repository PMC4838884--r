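#module fate
#module apoptosis
#module cycle
NODE FA fate
NODE FB fate
NODE DA1 fate
NODE DA2 fate
NODE DB1 fate
NODE DB2 fate
NODE AP apoptosis
NODE AE1 apoptosis
NODE SRV apoptosis
NODE CYC cycle
EDGE FA FA +
EDGE FB FB +
EDGE FA FB -
EDGE FB FA -
EDGE AP FA -
EDGE AP FB -
EDGE FA DA1 +
EDGE FA DA2 +
EDGE FB DB1 +
EDGE FB DB2 +
EDGE AP AP +
EDGE FA AP -
EDGE FB AP -
EDGE SRV AP -
EDGE AP SRV -
EDGE FA SRV +
EDGE FB SRV +
EDGE AP AE1 +
EDGE FA CYC +
EDGE FB CYC +
EDGE AP CYC -
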