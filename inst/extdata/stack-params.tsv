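pair1	pair2	dH	dS	dG37
AU	AU	-6.82	-0.018991	-0.93
AU	UA	-9.38	-0.026697	-1.1
UA	AU	-7.69	-0.020506	-1.33
UA	UA	-6.82	-0.018991	-0.93
CG	UA	-10.48	-0.027084	-2.08
CG	AU	-10.44	-0.026858	-2.11
GC	UA	-11.4	-0.029534	-2.24
GC	AU	-12.44	-0.032533	-2.35
CG	GC	-10.64	-0.026697	-2.36
GC	GC	-13.39	-0.032662	-3.26
GC	CG	-14.88	-0.03695	-3.42
CG	CG	-13.39	-0.032662	-3.26
UA	CG	-12.44	-0.032533	-2.35
UA	GC	-10.44	-0.026858	-2.11
AU	CG	-11.4	-0.029534	-2.24
AU	GC	-10.48	-0.027084	-2.08
AU	GU	-4.092	-0.011394	-0.558
AU	UG	-5.628	-0.016018	-0.66
UA	GU	-4.614	-0.012304	-0.798
UA	UG	-4.092	-0.011394	-0.558
CG	GU	-6.264	-0.016115	-1.266
CG	UG	-6.288	-0.01625	-1.248
GC	GU	-7.464	-0.01952	-1.41
GC	UG	-6.84	-0.01772	-1.344
GU	AU	-4.092	-0.011394	-0.558
GU	UA	-5.628	-0.016018	-0.66
GU	CG	-6.84	-0.01772	-1.344
GU	GC	-6.288	-0.01625	-1.248
GU	GU	-4.092	-0.011394	-0.558
GU	UG	-5.628	-0.016018	-0.66
UG	AU	-4.614	-0.012304	-0.798
UG	UA	-4.092	-0.011394	-0.558
UG	CG	-7.464	-0.01952	-1.41
UG	GC	-6.264	-0.016115	-1.266
UG	GU	-4.614	-0.012304	-0.798
UG	UG	-4.092	-0.011394	-0.558
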