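../matrices/BLOSUM62.txt -3.2 -0.1
../matrices/BLOSUM62.txt -10 -0.6
../matrices/PAM250.txt -3.2 -0.1
../matrices/PAM250.txt -10 -0.6
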