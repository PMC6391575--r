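RF00994	mir-1255	\N	miRNA mir-1255	synthetic	toy	50.00	50.10	49.90	toy entry	\N
RF00129	mir-103	\N	mir-103/107 microRNA precursor	synthetic	toy	50.00	50.10	49.90	toy entry	\N
RF00103	mir-1	\N	mir-1 microRNA precursor family	synthetic	toy	50.00	50.10	49.90	toy entry	\N
RF00446	mir-133	\N	mir-133 microRNA precursor family	synthetic	toy	50.00	50.10	49.90	toy entry	\N
RF00027	let-7	\N	let-7 microRNA precursor	synthetic	toy	50.00	50.10	49.90	toy entry	\N
RF90001	mir-555	\N	mir-555 microRNA precursor family	synthetic	toy	50.00	50.10	49.90	toy entry	mir555, MIR_555
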