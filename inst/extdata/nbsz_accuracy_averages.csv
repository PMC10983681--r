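model,method,mape
ets,bu,12.58
ets,tdfp,12.65
ets,tdha,12.62
ets,tdhp,12.43
ets,oc,12.57
arima,bu,12.0
arima,tdfp,11.3
arima,tdha,11.52
arima,tdhp,11.52
arima,oc,11.52
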