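bpd,max_uZ_mm,ratio_Z_printed_pct,t_uZ_s,uX_span_mm,t_uX_s,ratio_X_printed_pct
80,50.3580,128.90,0.1050,127.1100,0.1275,181.59
90,50.6840,126.71,0.0990,140.2100,0.1440,200.30
100,52.5090,131.27,0.0990,129.3800,0.1350,184.83
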