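# Synthetic stand-in for a host extracellular-exchange metabolite list.
# One metabolite id per line; replace with a curated list for real analyses.
hum_exchange_01
hum_exchange_02
hum_exchange_03
hum_exchange_04
hum_exchange_05
hum_exchange_06
hum_exchange_07
hum_exchange_08
hum_exchange_09
hum_exchange_10
hum_exchange_11
hum_exchange_12
hum_exchange_13
hum_exchange_14
hum_exchange_15
hum_exchange_16
hum_exchange_17
hum_exchange_18
hum_exchange_19
hum_exchange_20
hum_exchange_21
hum_exchange_22
hum_exchange_23
hum_exchange_24
hum_exchange_25
hum_exchange_26
hum_exchange_27
hum_exchange_28
hum_exchange_29
hum_exchange_30
hum_exchange_31
hum_exchange_32
hum_exchange_33
hum_exchange_34
hum_exchange_35
hum_exchange_36
hum_exchange_37
hum_exchange_38
hum_exchange_39
hum_exchange_40
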