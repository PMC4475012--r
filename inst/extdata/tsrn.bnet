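# CD4+ T-cell transcriptional-signaling regulatory network (TSRN), 18 nodes:
# 5 master transcription factors, 7 intrinsic cytokine signaling pathways,
# 6 extrinsic cytokine inputs. Pathway nodes are "signal transduced": active
# when the cytokine is present (made by the cell or supplied extrinsically)
# and not blocked. Inhibitions mediated by SOCS proteins are the
# pathway-level blocks listed in tsrn_socs_edges.csv; they are the edges
# removed in the TSRN_noSOCS variant.
#! inputs: IFNGe IL2e IL4e IL21e TGFBe IL10e
#! category: TBET transcription_factor
#! category: GATA3 transcription_factor
#! category: RORGT transcription_factor
#! category: FOXP3 transcription_factor
#! category: BCL6 transcription_factor
#! category: IFNG intrinsic_pathway
#! category: IL2 intrinsic_pathway
#! category: IL4 intrinsic_pathway
#! category: IL21 intrinsic_pathway
#! category: IL9 intrinsic_pathway
#! category: TGFB intrinsic_pathway
#! category: IL10 intrinsic_pathway
#! category: IFNGe extrinsic_cytokine
#! category: IL2e extrinsic_cytokine
#! category: IL4e extrinsic_cytokine
#! category: IL21e extrinsic_cytokine
#! category: TGFBe extrinsic_cytokine
#! category: IL10e extrinsic_cytokine
targets, factors
TBET, (TBET | IFNG) & ! GATA3
GATA3, (GATA3 | IL4) & ! TBET
RORGT, TGFB & (RORGT | IL21) & ! FOXP3 & ! TBET & ! GATA3 & ! IL10
FOXP3, (FOXP3 | TGFB) & IL2 & ! RORGT & ! IL21
BCL6, (BCL6 | IL21) & ! TBET & ! GATA3
IFNG, (TBET | IFNGe) & ! IL10
IL2, IL2e
IL4, ((GATA3 & ! TGFB) | IL4e) & ! TBET & ! IFNG & ! IL10
IL21, RORGT | BCL6 | IL21e
IL9, IL4 & TGFB & ! IL10
TGFB, TGFBe | FOXP3
IL10, IL10e | FOXP3
IFNGe, IFNGe
IL2e, IL2e
IL4e, IL4e
IL21e, IL21e
TGFBe, TGFBe
IL10e, IL10e
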