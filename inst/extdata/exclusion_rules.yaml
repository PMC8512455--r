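# Protein-exclusion configuration (editable).
#
# Accession lists below are a stand-in mapping of the named serum proteins to
# mouse UniProt accessions; adapt them to the accession space of your own
# search database. Protein-group ids are matched member-wise on
# semicolon-separated accessions.
contaminant_prefix: "CON__"
accessions:
  albumin:
    - P07724        # ALB_MOUSE serum albumin
  serotransferrin:
    - Q921I1        # TRFE_MOUSE serotransferrin
  igg:
    - P01868        # IGHG1_MOUSE Ig gamma-1 chain C region
    - P01863        # GCAA_MOUSE Ig gamma-2A chain C region (allele a)
    - P01864        # GCAB_MOUSE Ig gamma-2A chain C region (allele b)
    - P01867        # IGG2B_MOUSE Ig gamma-2B chain C region
    - P03987        # IGHG3_MOUSE Ig gamma-3 chain C region
    - P01837        # IGKC_MOUSE Ig kappa chain C region
rules:
  serum_tmt:
    # depletion leaves residual amounts of these high-abundance proteins,
    # so their intensities track depletion efficiency, not biology
    exclude_categories: [albumin, serotransferrin, igg]
    reason: "high-abundance/depletion-dependent"
    drop_contaminants: true
  sev_lfq:
    # highly variable serum proteins whose level tracks vesicle-isolation
    # efficiency; serotransferrin is retained in this assay
    exclude_categories: [albumin, igg]
    reason: "high-variability/isolation-dependent"
    drop_contaminants: true
  csf_lfq:
    exclude_categories: []
    reason: ""
    drop_contaminants: true
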