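Optional user-supplied data for the published-table reproduction.

Place exports of the study's supplementary tables (not redistributable
with the package) under a subdirectory named `supplementary/`, keyed by
their supplementary number:

  supplementary/S1.xlsx (or .tsv)   quantifiable-protein result sheet
                                    (geneName, Accession.No, logSAM*/logCON*)
  supplementary/S2..S7.*            raw per-replicate proteinGroups tables
  supplementary/S8.*                residue-by-position counts per
                                    fold-change group (group, residue, 13
                                    position columns)
  supplementary/S10.*               per-oocyte intensities (genotype, intensity)
  supplementary/S11.*               orientation counts (genotype, bioriented,
                                    monooriented)

Then run reproduce_supplementary(system.file("extdata", "supplementary",
package = "coseda")).
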