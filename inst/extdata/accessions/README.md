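Drop-in directory for deposited coordinate files used by the accession
integration checks (e.g. 1CKJ.pdb, 6PXN.pdb). Files are not bundled with
the package; obtain them from the PDB and place them here (or point
options(ck1switch.accession_dir = ...) at another directory). See
?locate_accession.
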