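# Catalog of the 85 crystal structures of the alpha/beta TCR analysis set
# (136 biological units in total across the deposited assemblies).
# bu_chains / alpha_range / beta_range are left blank: per-BU chain
# assignments and variable-domain ranges (IMGT V-domain boundaries) must
# be filled in against the locally downloaded coordinate files before
# load_manifest_complexes() can enumerate biological units.
pdb_id	file	bu_chains	alpha_range	beta_range	bound_state	species	tcr_type
2bnu	2bnu.pdb				u	h	1G4
2bnq	2bnq.pdb				1	h	1G4
2bnr	2bnr.pdb				1	h	1G4
2f54	2f54.pdb				1	h	1G4 AV-wt
2pyf	2pyf.pdb				u	h	1G4 c5c1
2pye	2pye.pdb				1	h	1G4 c5c1
2f53	2f53.pdb				1	h	1G4 c49c50
2p5w	2p5w.pdb				1	h	1G4 c58c62
2p5e	2p5e.pdb				1	h	1G4 c58c61
1zgl	1zgl.pdb				2	h	3A6
2gj6	2gj6.pdb				1	h	A6
1qsf	1qsf.pdb				1	h	A6
1qse	1qse.pdb				1	h	A6
3d3v	3d3v.pdb				1	h	A6
3d39	3d39.pdb				1	h	A6
1qrn	1qrn.pdb				1	h	A6
1ao7	1ao7.pdb				1	h	A6
3h9s	3h9s.pdb				1	h	A6
3pwp	3pwp.pdb				1	h	A6
3o4l	3o4l.pdb				1	h	AS01
1bd2	1bd2.pdb				1	h	B7
3ffc	3ffc.pdb				1	h	cf34
3dxa	3dxa.pdb				1	h	DM1
3dx9	3dx9.pdb				u	h	DM1
2ian	2ian.pdb				2	h	E8
2iam	2iam.pdb				2	h	E8
2ial	2ial.pdb				u	h	E8
2nx5	2nx5.pdb				1	h	ELS4
2nw2	2nw2.pdb				u	h	ELS4
1fyt	1fyt.pdb				2	h	HA1.7
1j8h	1j8h.pdb				2	h	HA1.7
3pl6	3pl6.pdb				1	h	Hy.1B1
2vlj	2vlj.pdb				1	h	JM22
2vlk	2vlk.pdb				1	h	JM22
1oga	1oga.pdb				1	h	JM22
2vlm	2vlm.pdb				u	h	JM22
2xn9	2xn9.pdb				s	h	JM22
2xna	2xna.pdb				s	h	JM22
2vlr	2vlr.pdb				1	h	JM22 S99bA
2esv	2esv.pdb				1	h	KK50.4
1mi5	1mi5.pdb				1	h	LC13
1kgc	1kgc.pdb				u	h	LC13
3kpr	3kpr.pdb				1	h	LC13
3kps	3kps.pdb				1	h	LC13
3hg1	3hg1.pdb				1	h	MEL5
2wbj	2wbj.pdb				2	h	OB.1A12
1ymm	1ymm.pdb				2	h	OB.1A12
3gsn	3gsn.pdb				1	h	RA14
2ak4	2ak4.pdb				1	h	SB27
3kxf	3kxf.pdb				1	h	SB27 K16Da
3o6f	3o6f.pdb				2	h	TCR MS2-3C8
3mv7	3mv7.pdb				1	h	TK3 wt
3mv8	3mv8.pdb				1	h	TK3 Q55H
3mv9	3mv9.pdb				1	h	TK3 Q55A
2pxy	2pxy.pdb				2	m	1934.4
3mff	3mff.pdb				u	m	1F1E8
3qiu	3qiu.pdb				2	m	226 TCR
3qiw	3qiw.pdb				2	m	226 TCR
3qib	3qib.pdb				1	m	2B4
3qjf	3qjf.pdb				u	m	2B4
1tcr	1tcr.pdb				u	m	2C
1g6r	1g6r.pdb				1	m	2C
1mwa	1mwa.pdb				1	m	2C
2ckb	2ckb.pdb				1	m	2C
2icw	2icw.pdb				s	m	2C T7
2oi9	2oi9.pdb				1	m	2C T7-wt-s
3e3q	3e3q.pdb				1	m	2C m13 T7-s
2e7l	2e7l.pdb				1	m	2C m6 T7-s
3e2h	3e2h.pdb				1	m	2C m67 T7-s
3c6l	3c6l.pdb				2	m	2W20
3qjh	3qjh.pdb				u	m	5c.c7
2uwe	2uwe.pdb				1	m	AHIII12.2
2jcc	2jcc.pdb				1	m	AHIII12.2
1lp9	1lp9.pdb				1	m	AHIII12.2
3c5z	3c5z.pdb				2	m	B3K506
1nam	1nam.pdb				1	m	BM3.3
1fo0	1fo0.pdb				1	m	BM3.3
2ol3	2ol3.pdb				1	m	BM3.3
2z31	2z31.pdb				2	m	cl19
1d9k	1d9k.pdb				2	m	D10
1kj2	1kj2.pdb				1	m	KB5-C20
1nfd	1nfd.pdb				u	m	N15
3mbe	3mbe.pdb				2	m	TCR 21.30
1u3h	1u3h.pdb				2	m	TCR172.10
3c60	3c60.pdb				2	m	YAe62
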