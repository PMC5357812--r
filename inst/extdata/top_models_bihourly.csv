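model,df,loglik,aicc,delta_aicc,weight
month + time + water + temp,27,-23481.89,47017.82,0,0.521
month + time + water + rain + temp,28,-23481.13,47018.30,0.48,0.409
month + sex + time + water + temp,28,-23483.52,47023.10,5.28,0.037
month + sex + time + water + rain + temp,29,-23482.77,47023.58,5.76,0.029
habitat + month + time + water + temp,34,-23480.30,47028.67,10.86,0.002
habitat + month + time + water + rain + temp,35,-23479.79,47029.65,11.83,0.001
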