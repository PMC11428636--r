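element_size_mm,element_count,v_max_mps,wss_max_pa,runtime_min
0.2,9248899,0.753678,19.67837,103
0.4,1753454,0.748364,20.14034,37
0.6,951802,0.741864,21.35883,31
0.8,766309,0.725355,22.67753,27
1,732146,0.753678,24.66996,25
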