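rsid_a	rsid_b	r2
rs000001	rs000002	0.883206443050876
rs000001	rs000003	0.949464692710899
rs000002	rs000003	0.887559764725156
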