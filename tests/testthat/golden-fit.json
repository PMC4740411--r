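{"parameters":[{"parameter":"(Intercept)","median":-0.0297119199980063,"lower":-0.101358175052248,"upper":0.0373023065206496,"geweke":-1.16367034716581,"rr":null,"rr_lower":null,"rr_upper":null},{"parameter":"tau2","median":0.0518409225968309,"lower":0.0105695519125809,"upper":0.148236365092764,"geweke":4.59162338783474,"rr":null,"rr_lower":null,"rr_upper":null},{"parameter":"rho","median":0.3354346584396,"lower":0.010591942910376,"upper":0.892168844041615,"geweke":-0.0992282923399856,"rr":null,"rr_lower":null,"rr_upper":null}],"acceptance":{"beta":0.438,"phi":0.274,"rho":0.81},"settings":{"nIter":600,"nBurnin":100,"thin":1,"seed":5,"nAreas":16,"covariates":[]}}
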