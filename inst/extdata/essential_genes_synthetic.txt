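rplA
rplB
rplC
rplD
rplE
rplF
rplI
rplJ
rplK
rplL
rplM
rplN
rplO
rplP
rplQ
rplR
rplS
rplT
rplU
rplV
rplW
rplX
rpmA
rpmB
rpmC
rpmD
rpmE
rpmF
rpmG
rpmH
rpmI
rpmJ
rpsB
rpsC
rpsD
rpsE
rpsF
rpsG
rpsH
rpsI
rpsJ
rpsK
rpsL
rpsM
rpsN
rpsO
rpsP
rpsQ
rpsR
rpsS
rpsT
alaS
argS
aspS
cysS
gltX
glyS
hisS
ileS
leuS
lysS
metG
pheS
pheT
proS
serS
thrS
trpS
tyrS
valS
rpoA
rpoB
rpoC
dnaA
dnaG
dnaN
dnaX
gyrA
gyrB
infA
infB
infC
tsf
tufA
fusA
frr
prfA
ffh
ftsY
secA
secE
secY
yidC
recA
ruvA
ruvB
uvrB
ligA
nusA
nusG
rnc
rpoD
smpB
tilS
ychF
engA
era
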