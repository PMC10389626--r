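family loglogistic
age_center 65.1
age_scale 10
formula.alpha ~age_s + scc + chemo + stage2 + stage3 + stage4 + r1r2
formula.eta ~age_s + female + educ_gt12 + scc + stage3 + stage4 + r1r2 + reop
formula.phi ~1
formula.gamma ~1
formula.rho ~1
alpha.(Intercept) -1.26
alpha.age_s 0.28
alpha.scc 0.58
alpha.chemo 0.45
alpha.stage2 1.57
alpha.stage3 2.25
alpha.stage4 2.37
alpha.r1r2 1.62
eta.(Intercept) 2.67
eta.age_s -0.15
eta.female 0.29
eta.educ_gt12 0.38
eta.scc -0.26
eta.stage3 -0.56
eta.stage4 -0.98
eta.r1r2 -0.62
eta.reop -0.46
phi.(Intercept) -0.76
gamma.(Intercept) -2.20
rho.(Intercept) -0.42
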