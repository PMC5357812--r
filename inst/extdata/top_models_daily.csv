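model,df,loglik,aicc,delta_aicc,weight
habitat + month + temp + water,21,-429.80,901.87,0,0.653
habitat + month + water,20,-431.64,903.52,1.65,0.286
habitat + month + sex + temp + water,22,-431.70,907.69,5.83,0.035
habitat + month + sex + water,21,-433.54,909.33,7.47,0.016
habitat + month + temp + water + rain,22,-433.26,910.80,8.93,0.007
habitat + month + water + rain,21,-435.33,912.93,11.06,0.003
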