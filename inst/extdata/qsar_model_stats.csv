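model,q2,onc,see,r2_fit,f,r_pred_sq,rmse,r2,r0_sq,r0p_sq,k,k_prime
CoMFA,0.897,7,0.050,0.983,229.50,0.948,0.074,0.950,0.946,0.936,0.998,1.002
CoMSIA,0.922,11,0.041,0.990,212.26,0.840,0.130,0.922,0.840,0.897,1.005,0.995
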