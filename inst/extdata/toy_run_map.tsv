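run_label	sample_id	time_point
TOY_t0.5	TOY	0.5
TOY_t1	TOY	1
TOY_t2	TOY	2
TOY_t6	TOY	6
TOY_t24	TOY	24
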