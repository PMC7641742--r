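resname	atom_a	atom_b
DA	OP3	P
DA	OP3	HOP3
DA	P	OP1
DA	P	OP2
DA	P	O5'
DA	OP2	HOP2
DA	O5'	C5'
DA	C5'	C4'
DA	C5'	H5'
DA	C5'	H5''
DA	C4'	O4'
DA	C4'	C3'
DA	C4'	H4'
DA	O4'	C1'
DA	C3'	O3'
DA	C3'	C2'
DA	C3'	H3'
DA	O3'	HO3'
DA	C2'	C1'
DA	C2'	H2'
DA	C2'	H2''
DA	C1'	N9
DA	C1'	H1'
DA	N9	C8
DA	N9	C4
DA	C8	N7
DA	C8	H8
DA	N7	C5
DA	C5	C6
DA	C5	C4
DA	C6	N6
DA	C6	N1
DA	N6	H61
DA	N6	H62
DA	N1	C2
DA	C2	N3
DA	C2	H2
DA	N3	C4
DC	OP3	P
DC	OP3	HOP3
DC	P	OP1
DC	P	OP2
DC	P	O5'
DC	OP2	HOP2
DC	O5'	C5'
DC	C5'	C4'
DC	C5'	H5'
DC	C5'	H5''
DC	C4'	O4'
DC	C4'	C3'
DC	C4'	H4'
DC	O4'	C1'
DC	C3'	O3'
DC	C3'	C2'
DC	C3'	H3'
DC	O3'	HO3'
DC	C2'	C1'
DC	C2'	H2'
DC	C2'	H2''
DC	C1'	N1
DC	C1'	H1'
DC	N1	C2
DC	N1	C6
DC	C2	O2
DC	C2	N3
DC	N3	C4
DC	C4	N4
DC	C4	C5
DC	N4	H41
DC	N4	H42
DC	C5	C6
DC	C5	H5
DC	C6	H6
DG	OP3	P
DG	OP3	HOP3
DG	P	OP1
DG	P	OP2
DG	P	O5'
DG	OP2	HOP2
DG	O5'	C5'
DG	C5'	C4'
DG	C5'	H5'
DG	C5'	H5''
DG	C4'	O4'
DG	C4'	C3'
DG	C4'	H4'
DG	O4'	C1'
DG	C3'	O3'
DG	C3'	C2'
DG	C3'	H3'
DG	O3'	HO3'
DG	C2'	C1'
DG	C2'	H2'
DG	C2'	H2''
DG	C1'	N9
DG	C1'	H1'
DG	N9	C8
DG	N9	C4
DG	C8	N7
DG	C8	H8
DG	N7	C5
DG	C5	C6
DG	C5	C4
DG	C6	O6
DG	C6	N1
DG	N1	C2
DG	N1	H1
DG	C2	N2
DG	C2	N3
DG	N2	H22
DG	N2	H21
DG	N3	C4
DT	OP3	P
DT	OP3	HOP3
DT	P	OP1
DT	P	OP2
DT	P	O5'
DT	OP2	HOP2
DT	O5'	C5'
DT	C5'	C4'
DT	C5'	H5'
DT	C5'	H5''
DT	C4'	O4'
DT	C4'	C3'
DT	C4'	H4'
DT	O4'	C1'
DT	C3'	O3'
DT	C3'	C2'
DT	C3'	H3'
DT	O3'	HO3'
DT	C2'	C1'
DT	C2'	H2'
DT	C2'	H2''
DT	C1'	N1
DT	C1'	H1'
DT	N1	C2
DT	N1	C6
DT	C2	O2
DT	C2	N3
DT	N3	C4
DT	N3	H3
DT	C4	O4
DT	C4	C5
DT	C5	C7
DT	C5	C6
DT	C7	H71
DT	C7	H72
DT	C7	H73
DT	C6	H6
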