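Deposited AT2R coordinate files are not redistributed with the package.

To run the worked example on the crystal structures, download the
agonist-bound (6JOD) and antagonist-bound (5UNG) entries into this
directory, e.g. from R:

    conformscape::fetch_at2r_structures("inst/extdata/pdb")

and reinstall the package so system.file() can find them.
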