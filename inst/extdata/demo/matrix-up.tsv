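id	c1	c2	c3	c4	c5	c6	c7	c8	c9	c10
g01	1	1	0	1	1	1	1	0	0	1
g02	1	1	1	1	0	1	1	1	1	1
g03	1	1	1	1	1	1	1	1	1	1
g04	0	0	0	1	0	0	0	1	0	0
g05	0	0	0	0	0	0	0	0	0	0
g06	0	0	0	0	0	0	0	0	0	0
g07	0	0	0	0	0	0	0	0	1	0
g08	0	0	0	0	0	0	0	0	0	0
g09	0	0	0	0	0	0	0	0	0	0
g10	0	0	0	0	0	0	0	0	0	0
g11	0	0	0	0	0	0	0	0	0	0
g12	0	0	0	0	0	0	0	0	0	0
g13	1	1	1	1	1	1	1	1	1	1
g14	0	0	0	0	0	0	0	0	0	0
g15	1	0	0	0	0	0	0	0	0	0
g16	0	0	0	0	0	0	0	0	0	0
g17	0	0	0	0	0	0	0	0	0	0
g18	0	0	0	0	1	0	0	0	0	0
g19	0	1	0	0	0	0	0	0	0	0
g20	0	0	0	0	1	1	0	1	0	0
g21	1	0	0	0	0	0	0	0	0	0
g22	0	0	0	0	0	0	0	0	0	0
g23	1	1	1	1	1	1	1	1	1	1
g24	0	0	0	0	0	0	0	0	0	0
g25	0	0	0	0	0	0	0	0	0	0
g26	0	1	0	0	0	0	0	0	0	0
g27	0	0	0	0	0	0	0	0	1	0
g28	0	0	0	0	0	0	0	0	0	0
g29	0	0	0	0	0	0	0	0	0	0
g30	0	0	1	0	0	0	0	0	0	0
g31	0	1	0	0	0	0	0	1	1	0
g32	0	0	0	0	0	0	0	0	0	0
g33	0	0	0	0	0	0	0	0	0	0
g34	0	0	0	0	0	0	0	0	0	0
g35	0	0	0	0	0	0	0	0	0	0
g36	0	0	0	0	0	0	0	0	0	0
g37	1	0	1	1	0	1	1	1	1	1
g38	0	0	0	0	0	0	0	0	0	0
g39	0	0	0	0	0	0	0	0	0	0
g40	0	0	0	0	0	0	0	0	0	0
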