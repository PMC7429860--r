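protein_id	sample_id	emPAI
AGO4a	veg_sam_1	0.31
AGO4b	veg_sam_1	0.12
DRM2	veg_sam_1	0.08
DCL3	veg_sam_1	0.05
RDR2	veg_sam_1	0.04
NRPD1	veg_sam_1	0.02
AGO4a	veg_sam_2	0.27
AGO4b	veg_sam_2	0.10
DRM2	veg_sam_2	0.09
DCL3	veg_sam_2	0.06
RDR2	veg_sam_2	NA
NRPD1	veg_sam_2	0.03
AGO4a	leaf_1	0.05
AGO4b	leaf_1	NA
DRM2	leaf_1	0.02
DCL3	leaf_1	0.01
RDR2	leaf_1	0.01
NRPD1	leaf_1	NA
AGO4a	leaf_2	0.04
AGO4b	leaf_2	0.02
DRM2	leaf_2	0.03
DCL3	leaf_2	NA
RDR2	leaf_2	0.01
NRPD1	leaf_2	0.01
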