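# Deposited mitochondrial data (not redistributed)

The real-data mitochondrial check in the test suite expects two files in
this directory, built from the study's deposited mitochondrial consensus
FASTAs (ENA project accession PRJEB51668):

- `mtdna_alignment.fasta` — the aligned mitochondrial consensus sequences
  (equal length, `N` for missing data).
- `mtdna_groups.tsv` — a group table (`#sample<TAB>group<TAB>role` header)
  assigning each sequence to haplogroup `T` or `F`.

These sequences are third-party deposited data and are not shipped with
the package; download them from ENA, align them, and place the two files
here (or install the package after doing so). The low-coverage Direkli17
consensus is excluded from the F-haplogroup comparison by the test itself.
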