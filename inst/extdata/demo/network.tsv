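g01	g02
g01	g03
g02	g03
g02	g04
g01	g04
g03	g05
g02	g05
g02	g06
g03	g06
g03	g07
g02	g07
g04	g08
g03	g08
g07	g09
g04	g09
g06	g10
g09	g10
g04	g11
g06	g11
g09	g12
g02	g12
g04	g13
g01	g13
g08	g14
g13	g14
g03	g15
g09	g15
g14	g16
g10	g16
g02	g17
g06	g17
g06	g18
g10	g18
g06	g19
g04	g19
g03	g20
g02	g20
g08	g21
g18	g21
g03	g22
g16	g22
g01	g23
g20	g23
g07	g24
g08	g24
g16	g25
g05	g25
g07	g26
g04	g26
g02	g27
g23	g27
g18	g28
g02	g28
g02	g29
g09	g29
g16	g30
g18	g30
g09	g31
g21	g31
g18	g32
g10	g32
g18	g33
g14	g33
g24	g34
g23	g34
g17	g35
g34	g35
g27	g36
g20	g36
g01	g37
g08	g37
g31	g38
g34	g38
g06	g39
g35	g39
g18	g40
g31	g40
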