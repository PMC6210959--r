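weir,model,r2_train,r2_test,rmse_train,rmse_test,aic_train,aic_test
Gangjeong-Goryeong,ELM1,0.61,0.47,8.6,14.5,371.2,452.2
Dalseong,ELM1,0.55,0.44,12.6,13.5,444.6,455.8
Hapcheon-Changnyeong,ELM1,0.38,0.41,15.3,13.1,461.3,436.1
Changnyeong-Haman,ELM1,0.29,0.36,16.6,12.4,469.0,421.9
Gangjeong-Goryeong,ELM2,0.71,0.45,6.8,13.8,333.8,446.2
Dalseong,ELM2,0.76,0.45,8.9,13.4,388.1,456.9
Hapcheon-Changnyeong,ELM2,0.44,0.43,14.6,13.1,455.8,437.5
Changnyeong-Haman,ELM2,0.32,0.46,16.3,11.4,468.3,410.5
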