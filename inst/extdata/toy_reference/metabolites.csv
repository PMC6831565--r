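metabolite,formula,neutral_mass
carnitine,C7H15NO3,161.105193
acetylcarnitine,C9H17NO4,203.115758
propionylcarnitine,C10H19NO4,217.131408
octanoylcarnitine,C15H29NO4,287.209658
decanoylcarnitine,C17H33NO4,315.240959
palmitoylcarnitine,C23H45NO4,399.334859
alpha-tocotrienol,C29H44O2,424.334131
gamma-tocotrienol,C28H42O2,410.318481
delta-tocotrienol,C27H40O2,396.302831
alpha-tocopherol,C29H50O2,430.381081
gamma-tocopherol,C28H48O2,416.365431
tryptophan,C11H12N2O2,204.089878
kynurenine,C10H12N2O3,208.084792
kynurenic acid,C10H7NO3,189.042593
3-hydroxykynurenine,C10H12N2O4,224.079707
xanthurenic acid,C10H7NO4,205.037508
quinolinic acid,C7H5NO4,167.021858
glucose,C6H12O6,180.063388
ribose,C5H10O5,150.052823
mannitol,C6H14O6,182.079038
gluconic acid,C6H12O7,196.058303
glucuronic acid,C6H10O7,194.042653
fructose 6-phosphate,C6H13O9P,260.029719
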