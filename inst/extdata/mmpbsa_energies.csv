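complex,e_vdw,e_vdw_sd,e_ele,e_ele_sd,g_pb,g_pb_sd,g_sa,g_sa_sd,g_binding,g_binding_sd
XO-Febuxostat,-175.32,8.81,-39.95,6.37,136.43,11.05,-18.20,0.73,-97.04,9.45
XO-44,-160.03,10.29,-107.25,10.15,189.25,11.17,-17.27,0.78,-95.30,8.32
XO-VS12,-195.31,9.21,-69.99,13.91,197.26,13.45,-20.27,0.81,-88.31,10.40
XO-VS16,-220.50,9.93,-28.10,8.40,109.67,10.71,-20.78,0.86,-159.71,11.41
XO-VS19,-152.19,8.97,-49.01,6.76,124.32,11.20,-19.03,0.86,-95.91,10.52
XO-VS26,-216.89,9.57,-40.34,8.46,127.33,14.15,-20.94,0.91,-150.84,9.61
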