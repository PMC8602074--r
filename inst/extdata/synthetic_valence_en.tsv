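good	0.8
great	0.9
love	0.9
happy	0.8
kind	0.6
safe	0.5
clean	0.4
fair	0.4
protect	0.5
respect	0.6
bad	-0.7
evil	-0.9
hate	-0.9
sad	-0.6
disgusting	-0.8
cruel	-0.8
unfair	-0.5
kill	-0.8
war	-0.7
filthy	-0.7
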