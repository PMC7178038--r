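>TmACP_like_synthetic 81-residue synthetic stand-in for a hyperthermophilic bacterial ACP (not a deposited sequence)
MSSREEIFGKVKTIISEKLGVDEDQVTETAKLKDDLGADSLDLEVLVMDFETEFGIKDDA
ADLAKDSTVGEIVSYIEAKLA
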