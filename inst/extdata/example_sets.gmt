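INFLAMMATORY_RESPONSE_SYNTH	synthetic inflammatory response set	g0001	g0002	g0003	g0004
CELL_CYCLE_SYNTH	synthetic cell-cycle set	g0005	g0006	g0007
STRESS_SYNTH	synthetic stress set	g0002	g0008	g0008	g0009
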