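name: toy_geo
description: >
  Toy assay-metadata data model used for tests and examples. Synthetic: a
  small stand-in for repository submission schemas describing sequencing
  experiments.
attributes:
  - name: Assay
    description: The measurement technology used to generate the data.
    values: [RNA-seq, ATAC-seq, whole genome sequencing]
    metadata: {type: text}
  - name: Species
    description: Organism from which the sample was derived.
    values: [Homo sapiens, Mus musculus]
    metadata: {type: text}
  - name: LibraryPreparationMethod
    description: Kit or protocol used to prepare the sequencing library.
    values: [TruSight Tumor Panel, NEBNext Ultra II, TruSight RNA Pan-Cancer Panel, 10x Genomics Chromium]
    metadata: {type: text}
  - name: Tissue
    description: Tissue of origin of the sample.
    values: [kidney, uterus, blood, brain]
    metadata: {type: text}
  - name: Platform
    description: Instrument platform used for sequencing.
    values: [Illumina NovaSeq 6000, Illumina HiSeq 2500, Oxford Nanopore PromethION]
    metadata: {type: text}
  - name: IndividualID
    description: De-identified identifier of the individual.
    values: []
    metadata: {type: text}
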