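# Crystal structures (user-supplied)

Place PDB-format files of the MntR crystal structures here (before package
installation) to enable crystal-structure comparisons:

- `2F5F.pdb`, `2F5C.pdb` — Mn2+-bound MntR
- `2EV6.pdb` — Zn2+-bound MntR
- `2HYF.pdb`, `2HYG.pdb` — apo MntR

Download from the Protein Data Bank, e.g.

    curl -O https://files.rcsb.org/download/2F5F.pdb

These entries are not redistributed with the package. With the files in
place, `crystal_rmsd("2F5F.pdb", "2EV6.pdb")` reports the chain-matched
common-residue Calpha RMSD.
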