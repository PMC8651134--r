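company,total_value_gbp,n_payments,n_practices,median_single_payment,q1,q3
Bayer,765987.77,998,773,434.50,217.20,869.00
Pfizer,360556.90,140,105,1412.10,236.00,3907.00
Eli Lilly,271139.00,260,185,200.00,168.00,3353.00
Sanofi Aventis,269965.82,149,126,1000.00,240.00,2400.00
AstraZeneca,153865.25,85,16,250.00,150.00,550.00
Boehringer Ingelheim,145070.58,213,146,392.00,177.60,640.00
Merck Sharp & Dohme,124062.80,63,50,800.00,195.80,4400.00
Takeda,112428.80,94,58,240.00,180.00,921.40
Napp,97743.39,235,212,38.49,28.90,111.73
Servier,96162.40,62,61,1567.00,576.00,1567.00
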