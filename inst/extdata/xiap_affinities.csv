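complex_id,ic50_nM,dg_exp_printed,dg_pred_hmr,dg_pred_hmr_ie,exclude
5C7C,5500,-7.29,-37.4,-17.6,FALSE
5M6M,44,-10.20,-43.0,-24.9,FALSE
5OQW,40,-10.26,-43.9,-24.2,FALSE
5M6L,5.1,-11.49,-44.7,-25.6,FALSE
AVPI,320,-8.91,-39.5,-22.8,TRUE
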