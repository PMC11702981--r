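sample	site	depth	alt	hq_alt	expected_percent
example_1	chr17:example_site_1	98	44	44	45
example_2	chr17:example_site_2	100	35	35	35
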