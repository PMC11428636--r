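element_size_mm,element_count,v_max_mps,wss_max_pa,runtime_min
0.2,7030641,0.7200,21.8233293,222
0.4,1148142,0.7075,22.3736838,50
0.6,547059,0.6854,23.0381622,35
0.8,405490,0.6442,23.6513115,31
1,369728,0.5607,26.7444558,30
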