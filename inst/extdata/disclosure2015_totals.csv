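quantity,value
n_payments_total,2945
value_total_gbp,2726017.77
n_recipient_practices_total,1790
n_payments_excluded,198
value_excluded_gbp,166351.74
n_practices_excluded,147
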