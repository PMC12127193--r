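coagulation_like	synthetic gene set	P0001	P0003	P0005	P0007	P0009	P0011	P0013	P0015	P0017	P0019	P0021	P0023
complement_like	synthetic gene set	P0002	P0004	P0006	P0008	P0010	P0012	P0014	P0016	P0018	P0020
adhesion_like	synthetic gene set	P0005	P0010	P0015	P0020	P0025	P0030	P0035	P0040
keratin_axis	synthetic gene set	P0001	P0002	P0003	P0026	P0027	P0028	P0029
broad_panel	synthetic gene set	P0002	P0005	P0008	P0011	P0014	P0017	P0020	P0023	P0026	P0029	P0032	P0035	P0038
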