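go_term	slim_bin
GO:0007155	cell adhesion
GO:0022610	cell adhesion
GO:0007049	cell cycle
GO:0051301	cell cycle
GO:0008219	death
GO:0006915	death
GO:0019538	protein metabolism
GO:0006412	protein metabolism
GO:0016070	RNA metabolism
GO:0006950	stress response
GO:0016043	cell organization & biogenesis
GO:0008152	other metabolic processes
GO:0008283	cell proliferation
GO:0007165	signal transduction
GO:0006810	transport
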