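pop	lat	lon
JP	33.8	132.8
HI	22.1	-159.6
ST	37.4	-122.2
SD	32.7	-117.2
FL	27.8	-82.3
NC	36.4	-81.3
MI	42.6	-86.1
SP	41.4	2.2
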