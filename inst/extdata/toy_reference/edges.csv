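from,to
carnitine,acetylcarnitine
carnitine,propionylcarnitine
carnitine,octanoylcarnitine
carnitine,decanoylcarnitine
carnitine,palmitoylcarnitine
octanoylcarnitine,decanoylcarnitine
alpha-tocopherol,alpha-tocotrienol
alpha-tocotrienol,gamma-tocotrienol
gamma-tocotrienol,delta-tocotrienol
alpha-tocopherol,gamma-tocopherol
tryptophan,kynurenine
kynurenine,kynurenic acid
kynurenine,3-hydroxykynurenine
3-hydroxykynurenine,xanthurenic acid
3-hydroxykynurenine,quinolinic acid
glucose,fructose 6-phosphate
glucose,gluconic acid
gluconic acid,glucuronic acid
glucose,ribose
glucose,mannitol
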