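prefix,class,category
mex,AMR,efflux
opr,AMR,efflux
opm,AMR,efflux
acr,AMR,efflux
oqx,AMR,efflux
mdt,AMR,efflux
bla,AMR,beta_lactamase
fos,AMR,fosfomycin
mar,AMR,regulator
ram,AMR,regulator
cpx,AMR,regulator
crp,AMR,regulator
fli,VF,motility
flg,VF,motility
vip,VF,secretion
hcp,VF,secretion
clpv,VF,secretion
alg,VF,biofilm
pil,VF,biofilm
waa,VF,biofilm
csg,VF,adhesion
omp,VF,membrane
ent,VF,siderophore
pvd,VF,siderophore
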