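population,total_load
Kodi,0.09325
Lamboya,0.11078
Loli,0.23837
Wanokaka,0.09463
Mamboro,0.16669
Anakalang,0.14461
Wunga,0.17271
Rindi,0.0428
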