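# Starter keyword list for adaptation-gene flagging: gene families tied to
# oxidative, osmotic, temperature and general stress responses in extreme
# environments.  Matching is case-insensitive substring; extend or replace
# freely (one term per line).
rubrerythrin
ferritin
Fe-S oxidoreductase
DPS
OxyR
peroxide
peroxidase
catalase
superoxide dismutase
oxidative stress
thioredoxin
glutaredoxin
cold shock
heat shock
chaperone
osmoprotectant
trehalose
glycine betaine
compatible solute
halotolerance
sigma factor RpoS
universal stress protein
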