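>GAS_synthetic STAT1 GAS (synthetic matrix; TTCNNNGAA class, consensus TTCCGGGAA)
A [ 5 5 5 20 25 25 5 85 85 ]
C [ 5 5 85 40 20 20 5 5 5 ]
G [ 5 5 5 25 40 40 85 5 5 ]
T [ 85 85 5 15 15 15 5 5 5 ]
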