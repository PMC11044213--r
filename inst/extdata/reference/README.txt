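Drop locally fetched structure files here (or into the installed copy of
this directory) to score the published reference set with
fodm::reference_targets():

  7LUP 1JMU 4MCX 4ABL 1KUF 3OQC 1V4V 4AV3 2K4T 7VWX

as <id>.pdb or <id>.cif, e.g. from https://files.rcsb.org/download/7LUP.cif
These entries are multi-megabyte deposited structures and are not shipped
with the package.
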