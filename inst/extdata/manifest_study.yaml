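# Ensemble docking design of the triple-helix study: 21 congeneric
# ligands docked with two programs (250 poses each) against 11 curated
# conformations of Site 1 and 6 of Site 2 (retained MD centroids plus the
# crystal conformation per site).
sites:
- site_tag: S1
  n_conformations: 11
- site_tag: S2
  n_conformations: 6
programs:
- autodock_gpu
- rdock
poses_per_program: 250
ligand_ids:
- lig01
- lig02
- lig03
- lig04
- lig05
- lig06
- lig07
- lig08
- lig09
- lig10
- lig11
- lig12
- lig13
- lig14
- lig15
- lig16
- lig17
- lig18
- lig19
- lig20
- lig21
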