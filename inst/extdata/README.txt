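synthetic_holo_cnbb.pdb / synthetic_camp_cnbb.pdb
  SYNTHETIC stand-in fragments, not deposited PDB entries. Each places the
  pocket landmark pair (Ala360 CB, Leu351 CG) at the literature landmark
  separation for the holoenzyme (open, 6.9 A) and cAMP-bound (closed,
  4.9 A) states of a CNB-B phosphate-binding cassette, so that the
  distance-measurement machinery can be exercised at 0.1 A reporting
  precision without network access to the PDB. All other coordinates are
  arbitrary filler.
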