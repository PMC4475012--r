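# Minimal CD4+ T-cell transcriptional regulatory network (TRN).
# Five master regulators; no extrinsic inputs. RORGT and BCL6 have no
# sustaining transcriptional activator within this core (RORGT lacks any
# positive interaction; BCL6 autoregulation is unresolved), so their rules
# decay to 0; their inhibitory influence on other factors is transient.
#! inputs:
#! category: TBET transcription_factor
#! category: GATA3 transcription_factor
#! category: RORGT transcription_factor
#! category: FOXP3 transcription_factor
#! category: BCL6 transcription_factor
targets, factors
TBET, TBET & ! GATA3 & ! BCL6
GATA3, GATA3 & ! TBET & ! BCL6
RORGT, 0
FOXP3, FOXP3 & ! RORGT
BCL6, 0
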