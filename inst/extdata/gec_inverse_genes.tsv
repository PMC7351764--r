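gene_id	fc_wt	p_wt	fc_as	p_as
Ankrd37	1.404	0.0450	-1.64	0.0036
Arg1	3.398	0.0000	-1.715	0.0008
Nudt1	1.401	0.0300	-1.729	0.0056
Plet1	1.944	0.0090	-1.524	0.0091
Pleppr3	2.882	0.0018	-1.981	0.0166
Purg	1.392	0.0413	-1.259	0.0019
Serpinf1	2.718	0.0053	-2.035	0.0000
Stx19	2.481	0.0005	-1.869	0.0002
Ttll3	1.866	0.0220	-3.948	0.0002
Wdr95	2.691	0.0113	-1.402	0.0259
Zbtb16	1.617	0.0323	-1.397	0.0081
A4galt	-1.958	0.0323	4.402	0.0000
Aif1l	-1.119	0.0465	1.073	0.0033
Ak1	-1.251	0.0412	1.890	0.0000
Col1a2	-1.312	0.0251	1.194	0.0028
Efna4	-2.971	0.0183	3.446	0.0000
Enpep	-1.660	0.0132	1.323	0.0027
Grin3a	-2.858	0.0018	1.521	0.0113
Loxl2	-1.376	0.0374	4.382	0.0000
Oplah	-1.421	0.0269	1.671	0.0012
Polr2f	-1.673	0.0214	1.122	0.0191
Rassf10	-2.051	0.0012	1.353	0.0225
Rbpms2	-1.306	0.0278	1.778	0.0016
Rdh1	-2.638	0.0008	1.516	0.0188
Trpc6	-3.317	0.0359	5.304	0.0000
Tyro3	-2.910	0.0129	1.413	0.0106
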