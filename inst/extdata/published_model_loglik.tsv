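model	loglik	k_extra
delta	-63.12	1
linear	-63.11	1
two_rate	-60.73	2
null	-63.17	0
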