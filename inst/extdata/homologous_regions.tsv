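# Editable default homology configuration: 27 shared region names with lobe
# assignments. atlas_label is an identity placeholder -- replace it with the
# labels of the human and macaque parcellations actually in use (several
# atlas labels may map to one homolog; strengths are summed).
species	atlas_label	homolog	lobe
human	PMv/F5	PMv/F5	frontal
human	PMd	PMd	frontal
human	pre-SMA	pre-SMA	frontal
human	BA44	BA44	frontal
human	BA45	BA45	frontal
human	FEF	FEF	frontal
human	AIP	AIP	parietal
human	LIP	LIP	parietal
human	VIP	VIP	parietal
human	MIP	MIP	parietal
human	PFm	PFm	parietal
human	BA7A	BA7A	parietal
human	BA7m	BA7m	parietal
human	V6A	V6A	parietal
human	Tpt	Tpt	parietal
human	TE	TE	temporal
human	TEO	TEO	temporal
human	STP	STP	temporal
human	STS	STS	temporal
human	parabelt	parabelt	temporal
human	perirhinal	perirhinal	temporal
human	temporal-pole	temporal-pole	temporal
human	V1	V1	occipital
human	V2	V2	occipital
human	V3	V3	occipital
human	V3A	V3A	occipital
human	V4	V4	occipital
macaque	PMv/F5	PMv/F5	frontal
macaque	PMd	PMd	frontal
macaque	pre-SMA	pre-SMA	frontal
macaque	BA44	BA44	frontal
macaque	BA45	BA45	frontal
macaque	FEF	FEF	frontal
macaque	AIP	AIP	parietal
macaque	LIP	LIP	parietal
macaque	VIP	VIP	parietal
macaque	MIP	MIP	parietal
macaque	PFm	PFm	parietal
macaque	BA7A	BA7A	parietal
macaque	BA7m	BA7m	parietal
macaque	V6A	V6A	parietal
macaque	Tpt	Tpt	parietal
macaque	TE	TE	temporal
macaque	TEO	TEO	temporal
macaque	STP	STP	temporal
macaque	STS	STS	temporal
macaque	parabelt	parabelt	temporal
macaque	perirhinal	perirhinal	temporal
macaque	temporal-pole	temporal-pole	temporal
macaque	V1	V1	occipital
macaque	V2	V2	occipital
macaque	V3	V3	occipital
macaque	V3A	V3A	occipital
macaque	V4	V4	occipital
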