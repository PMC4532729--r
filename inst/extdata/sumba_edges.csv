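pop_a,pop_b,label,weight,theta
Kodi,Loli,1,0.01113,0.7624459
Kodi,Lamboya,2,0.02481,1.943735
Lamboya,Loli,3,0.06764,1.875696
Lamboya,Wanokaka,4,0.01297,2.187413
Loli,Wanokaka,5,0.06614,1.400967
Anakalang,Loli,6,0.0461,1.189525
Anakalang,Wanokaka,7,0.0098,1.681032
Rindi,Wanokaka,8,0.00572,1.013773
Anakalang,Rindi,9,0.01157,0.1476047
Rindi,Wunga,10,0.02015,2.743607
Anakalang,Wunga,11,0.04181,1.337191
Mamboro,Wunga,12,0.06872,2.014021
Anakalang,Mamboro,13,0.03533,1.927833
Loli,Mamboro,14,0.04736,1.054552
Kodi,Mamboro,15,0.01528,1.286779
Kodi,Wunga,16,0.03312,0.1883666
Kodi,Rindi,17,0.00891,2.101859
Lamboya,Rindi,18,0.00536,0.2763413
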