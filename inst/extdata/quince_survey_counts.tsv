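quantity	value
assembly_total_length_bp	488422409
estimated_genome_size_bp	686000000
n_contigs	303932
n50_bp	2435
ssr_mono	171414
ssr_di	117091
ssr_tri	15268
ssr_tetra	3081
ssr_penta	833
ssr_hexa	484
ssr_total	308171
ssr_di_AT	27583
tf_arabidopsis_identified	2686
tf_arabidopsis_total	2757
tf_rice_identified	2981
tf_rice_total	3119
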