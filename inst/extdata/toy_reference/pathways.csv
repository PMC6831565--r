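pathway,metabolite
carnitine shuttle,carnitine
carnitine shuttle,acetylcarnitine
carnitine shuttle,propionylcarnitine
carnitine shuttle,octanoylcarnitine
carnitine shuttle,decanoylcarnitine
carnitine shuttle,palmitoylcarnitine
vitamin E metabolism,alpha-tocotrienol
vitamin E metabolism,gamma-tocotrienol
vitamin E metabolism,delta-tocotrienol
vitamin E metabolism,alpha-tocopherol
vitamin E metabolism,gamma-tocopherol
kynurenine pathway,tryptophan
kynurenine pathway,kynurenine
kynurenine pathway,kynurenic acid
kynurenine pathway,3-hydroxykynurenine
kynurenine pathway,xanthurenic acid
kynurenine pathway,quinolinic acid
monosaccharide metabolism,glucose
monosaccharide metabolism,ribose
monosaccharide metabolism,mannitol
monosaccharide metabolism,gluconic acid
monosaccharide metabolism,glucuronic acid
monosaccharide metabolism,fructose 6-phosphate
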